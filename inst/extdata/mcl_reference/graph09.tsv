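gene_a	gene_b	r
n01	n04	0.838
n01	n07	0.91
n01	n09	0.974
n01	n10	0.967
n01	n11	0.962
n01	n12	0.873
n01	n14	0.941
n01	n15	0.841
n01	n17	0.863
n01	n18	0.93
n01	n19	0.896
n01	n20	0.892
n02	n04	0.863
n02	n07	0.83
n02	n10	0.923
n02	n11	0.944
n02	n13	0.889
n02	n14	0.834
n02	n15	0.951
n02	n17	0.847
n02	n18	0.94
n02	n19	0.909
n02	n20	0.954
n02	n27	0.812
n03	n05	0.885
n03	n06	0.942
n03	n07	0.881
n03	n08	0.837
n03	n09	0.877
n03	n12	0.953
n03	n14	0.891
n03	n16	0.966
n03	n18	0.976
n03	n19	0.907
n03	n28	0.819
n03	n47	0.822
n03	n60	0.819
n04	n07	0.833
n04	n08	0.847
n04	n09	0.888
n04	n13	0.956
n04	n14	0.941
n04	n15	0.884
n04	n16	0.973
n04	n17	0.923
n05	n08	0.837
n05	n10	0.942
n05	n13	0.856
n05	n15	0.889
n05	n16	0.913
n05	n17	0.855
n05	n18	0.838
n05	n19	0.903
n05	n20	0.869
n05	n33	0.818
n05	n55	0.829
n06	n07	0.966
n06	n09	0.955
n06	n11	0.849
n06	n13	0.862
n06	n14	0.866
n06	n17	0.871
n06	n18	0.964
n06	n19	0.838
n06	n20	0.903
n06	n40	0.812
n07	n08	0.855
n07	n10	0.821
n07	n12	0.948
n07	n14	0.865
n07	n15	0.893
n07	n16	0.87
n07	n17	0.916
n07	n18	0.884
n07	n20	0.907
n07	n23	0.801
n07	n28	0.831
n07	n42	0.827
n08	n09	0.822
n08	n10	0.883
n08	n11	0.898
n08	n14	0.866
n08	n15	0.968
n08	n16	0.975
n08	n19	0.901
n08	n20	0.965
n08	n31	0.81
n09	n10	0.949
n09	n11	0.881
n09	n15	0.946
n09	n16	0.933
n09	n17	0.946
n09	n18	0.962
n09	n19	0.835
n09	n20	0.937
n09	n43	0.828
n10	n12	0.897
n10	n13	0.83
n10	n14	0.947
n10	n16	0.825
n10	n18	0.858
n10	n19	0.96
n10	n20	0.977
n10	n43	0.816
n11	n13	0.859
n11	n14	0.929
n11	n15	0.885
n11	n18	0.933
n11	n20	0.877
n11	n49	0.837
n12	n13	0.976
n12	n14	0.9
n12	n15	0.832
n12	n16	0.876
n12	n17	0.856
n12	n18	0.829
n12	n20	0.937
n12	n30	0.835
n13	n15	0.968
n13	n16	0.929
n13	n17	0.922
n13	n31	0.805
n13	n50	0.802
n13	n53	0.809
n13	n54	0.813
n14	n16	0.959
n14	n18	0.895
n14	n19	0.943
n14	n20	0.863
n15	n16	0.935
n15	n17	0.927
n15	n18	0.875
n15	n56	0.822
n16	n17	0.865
n16	n20	0.895
n16	n30	0.839
n16	n38	0.827
n17	n18	0.872
n17	n36	0.838
n17	n51	0.838
n18	n20	0.851
n19	n56	0.81
n21	n22	0.884
n21	n25	0.847
n21	n27	0.843
n21	n28	0.846
n21	n29	0.886
n21	n32	0.835
n21	n33	0.862
n21	n35	0.9
n21	n36	0.867
n21	n39	0.831
n21	n40	0.827
n22	n24	0.854
n22	n27	0.911
n22	n28	0.875
n22	n30	0.854
n22	n31	0.862
n22	n32	0.892
n22	n33	0.931
n22	n34	0.847
n22	n38	0.971
n22	n40	0.847
n23	n25	0.835
n23	n26	0.947
n23	n27	0.848
n23	n28	0.92
n23	n29	0.833
n23	n31	0.976
n23	n32	0.842
n23	n33	0.833
n23	n35	0.876
n23	n36	0.863
n23	n37	0.938
n23	n39	0.945
n23	n60	0.806
n24	n25	0.855
n24	n27	0.964
n24	n29	0.961
n24	n30	0.911
n24	n34	0.837
n24	n36	0.823
n24	n38	0.892
n24	n39	0.851
n24	n40	0.978
n24	n49	0.822
n25	n27	0.914
n25	n29	0.889
n25	n31	0.841
n25	n32	0.956
n25	n33	0.902
n25	n34	0.966
n25	n36	0.92
n25	n38	0.898
n25	n40	0.961
n26	n27	0.864
n26	n31	0.938
n26	n32	0.943
n26	n33	0.823
n26	n34	0.959
n26	n35	0.945
n26	n36	0.831
n26	n37	0.97
n26	n39	0.938
n26	n40	0.844
n26	n58	0.808
n27	n30	0.974
n27	n31	0.941
n27	n33	0.854
n27	n35	0.844
n27	n36	0.89
n27	n37	0.822
n27	n38	0.899
n28	n29	0.864
n28	n34	0.917
n28	n35	0.939
n28	n36	0.957
n28	n38	0.895
n28	n39	0.862
n28	n40	0.911
n29	n32	0.909
n29	n33	0.97
n29	n34	0.933
n29	n35	0.92
n29	n36	0.877
n29	n37	0.963
n29	n38	0.885
n29	n40	0.937
n29	n42	0.819
n29	n54	0.827
n30	n34	0.924
n30	n36	0.898
n30	n39	0.93
n30	n42	0.814
n31	n32	0.898
n31	n33	0.897
n31	n34	0.83
n31	n35	0.824
n31	n36	0.951
n31	n37	0.898
n31	n39	0.881
n31	n55	0.822
n32	n34	0.968
n32	n35	0.962
n32	n36	0.977
n32	n38	0.942
n32	n39	0.95
n32	n40	0.966
n33	n36	0.9
n33	n37	0.849
n33	n38	0.95
n33	n40	0.898
n34	n35	0.92
n34	n36	0.848
n34	n37	0.891
n34	n38	0.834
n34	n40	0.918
n35	n36	0.923
n35	n37	0.962
n35	n39	0.915
n36	n38	0.924
n36	n55	0.817
n37	n39	0.828
n37	n40	0.853
n37	n53	0.822
n38	n39	0.975
n38	n40	0.845
n41	n42	0.832
n41	n43	0.83
n41	n44	0.971
n41	n45	0.979
n41	n46	0.826
n41	n47	0.836
n41	n48	0.971
n41	n51	0.971
n41	n53	0.951
n41	n55	0.882
n41	n56	0.857
n41	n57	0.889
n41	n59	0.948
n41	n60	0.948
n42	n43	0.838
n42	n44	0.857
n42	n46	0.939
n42	n49	0.961
n42	n50	0.968
n42	n51	0.838
n42	n52	0.84
n42	n56	0.844
n43	n45	0.939
n43	n48	0.891
n43	n49	0.838
n43	n50	0.824
n43	n51	0.898
n43	n52	0.942
n43	n54	0.881
n43	n57	0.856
n43	n58	0.868
n43	n59	0.926
n44	n45	0.97
n44	n47	0.852
n44	n48	0.963
n44	n50	0.948
n44	n51	0.898
n44	n54	0.828
n44	n57	0.929
n44	n58	0.879
n44	n59	0.842
n44	n60	0.882
n45	n48	0.885
n45	n49	0.829
n45	n50	0.822
n45	n51	0.831
n45	n53	0.953
n45	n54	0.953
n45	n57	0.915
n45	n58	0.824
n45	n59	0.957
n45	n60	0.91
n46	n47	0.96
n46	n48	0.885
n46	n49	0.926
n46	n50	0.955
n46	n53	0.956
n46	n54	0.822
n46	n55	0.96
n46	n56	0.853
n46	n59	0.925
n46	n60	0.979
n47	n48	0.822
n47	n49	0.95
n47	n50	0.958
n47	n51	0.823
n47	n52	0.928
n47	n56	0.891
n47	n58	0.876
n47	n59	0.832
n47	n60	0.88
n48	n50	0.831
n48	n52	0.978
n48	n53	0.911
n48	n54	0.842
n48	n56	0.896
n48	n57	0.828
n48	n58	0.855
n48	n59	0.838
n48	n60	0.966
n49	n50	0.832
n49	n52	0.931
n49	n54	0.902
n49	n56	0.861
n49	n59	0.923
n50	n53	0.85
n50	n54	0.871
n50	n56	0.971
n50	n58	0.963
n50	n60	0.856
n51	n52	0.972
n51	n53	0.908
n51	n54	0.846
n51	n55	0.847
n51	n57	0.923
n52	n54	0.877
n52	n55	0.92
n52	n57	0.832
n52	n58	0.908
n52	n59	0.935
n52	n60	0.835
n53	n54	0.919
n53	n55	0.953
n53	n57	0.884
n53	n58	0.84
n53	n59	0.884
n53	n60	0.959
n54	n56	0.977
n54	n57	0.952
n54	n60	0.98
n55	n57	0.924
n55	n58	0.822
n55	n60	0.892
n56	n57	0.873
n56	n60	0.92
n57	n58	0.897
n58	n59	0.974
n59	n60	0.97
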