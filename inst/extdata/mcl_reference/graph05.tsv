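gene_a	gene_b	r
n01	n02	0.913
n01	n03	0.907
n01	n04	0.921
n01	n05	0.886
n01	n06	0.875
n01	n07	0.861
n01	n08	0.842
n01	n10	0.884
n01	n11	0.929
n01	n12	0.966
n01	n14	0.938
n01	n16	0.959
n01	n17	0.947
n01	n19	0.84
n02	n03	0.956
n02	n06	0.931
n02	n07	0.857
n02	n10	0.91
n02	n11	0.978
n02	n13	0.963
n02	n14	0.932
n02	n16	0.842
n02	n17	0.832
n02	n19	0.908
n02	n44	0.804
n03	n05	0.821
n03	n06	0.844
n03	n07	0.842
n03	n08	0.907
n03	n09	0.875
n03	n10	0.926
n03	n13	0.978
n03	n14	0.864
n03	n18	0.947
n03	n19	0.957
n03	n20	0.825
n03	n38	0.806
n04	n09	0.889
n04	n11	0.822
n04	n12	0.936
n04	n15	0.975
n04	n17	0.947
n04	n18	0.903
n04	n48	0.827
n05	n07	0.888
n05	n10	0.95
n05	n11	0.933
n05	n14	0.893
n05	n15	0.881
n05	n16	0.826
n05	n17	0.913
n05	n20	0.968
n06	n07	0.952
n06	n08	0.831
n06	n09	0.823
n06	n13	0.906
n06	n14	0.931
n06	n17	0.856
n06	n20	0.924
n07	n08	0.868
n07	n10	0.915
n07	n11	0.824
n07	n12	0.865
n07	n13	0.892
n07	n15	0.908
n07	n17	0.923
n07	n18	0.938
n07	n20	0.846
n08	n10	0.922
n08	n11	0.886
n08	n12	0.861
n08	n14	0.971
n08	n15	0.968
n08	n18	0.974
n08	n20	0.863
n09	n10	0.843
n09	n12	0.949
n09	n14	0.945
n09	n15	0.884
n09	n16	0.937
n09	n17	0.858
n09	n18	0.863
n09	n19	0.91
n09	n20	0.84
n09	n25	0.813
n10	n11	0.826
n10	n12	0.868
n10	n13	0.887
n10	n15	0.907
n10	n18	0.863
n10	n55	0.803
n11	n14	0.953
n11	n15	0.909
n11	n16	0.963
n11	n17	0.96
n12	n13	0.959
n12	n15	0.841
n12	n17	0.952
n12	n18	0.932
n12	n19	0.872
n12	n20	0.844
n13	n16	0.956
n13	n17	0.977
n13	n18	0.861
n13	n19	0.872
n13	n42	0.814
n14	n16	0.878
n14	n18	0.911
n14	n19	0.925
n14	n20	0.92
n15	n16	0.979
n15	n17	0.855
n15	n18	0.959
n15	n19	0.977
n16	n19	0.829
n16	n20	0.838
n17	n18	0.949
n17	n19	0.906
n17	n20	0.925
n17	n33	0.804
n18	n19	0.878
n18	n35	0.812
n19	n20	0.902
n19	n32	0.832
n19	n46	0.822
n19	n54	0.826
n19	n60	0.823
n20	n41	0.811
n21	n24	0.875
n21	n27	0.915
n21	n28	0.958
n21	n29	0.833
n21	n30	0.916
n21	n31	0.905
n21	n33	0.959
n21	n35	0.88
n21	n37	0.842
n21	n38	0.954
n21	n39	0.958
n21	n40	0.822
n22	n23	0.953
n22	n24	0.848
n22	n26	0.884
n22	n27	0.839
n22	n31	0.903
n22	n32	0.918
n22	n38	0.864
n22	n39	0.977
n22	n40	0.943
n23	n24	0.89
n23	n25	0.824
n23	n26	0.925
n23	n27	0.874
n23	n29	0.832
n23	n31	0.9
n23	n32	0.911
n23	n33	0.891
n23	n34	0.94
n23	n35	0.846
n23	n37	0.865
n23	n38	0.87
n23	n39	0.948
n23	n40	0.938
n24	n26	0.902
n24	n27	0.911
n24	n28	0.85
n24	n29	0.861
n24	n30	0.945
n24	n31	0.946
n24	n33	0.826
n24	n35	0.961
n24	n36	0.943
n24	n37	0.852
n25	n26	0.863
n25	n27	0.959
n25	n29	0.865
n25	n32	0.879
n25	n37	0.93
n25	n38	0.836
n25	n39	0.919
n25	n40	0.948
n26	n27	0.959
n26	n30	0.839
n26	n31	0.922
n26	n32	0.835
n26	n33	0.899
n26	n34	0.842
n26	n35	0.928
n26	n37	0.961
n26	n39	0.911
n26	n42	0.81
n26	n49	0.827
n27	n28	0.841
n27	n29	0.968
n27	n31	0.871
n27	n32	0.953
n27	n34	0.94
n27	n36	0.898
n27	n38	0.942
n27	n50	0.84
n28	n29	0.907
n28	n30	0.873
n28	n32	0.948
n28	n33	0.828
n28	n34	0.867
n28	n35	0.965
n28	n39	0.862
n28	n40	0.9
n29	n30	0.824
n29	n31	0.825
n29	n32	0.841
n29	n35	0.936
n29	n38	0.822
n29	n40	0.857
n30	n37	0.936
n30	n39	0.893
n31	n32	0.904
n31	n33	0.847
n31	n34	0.87
n31	n35	0.891
n31	n36	0.855
n31	n37	0.836
n31	n38	0.829
n31	n39	0.926
n32	n33	0.837
n32	n34	0.892
n32	n35	0.89
n32	n36	0.979
n32	n37	0.955
n32	n38	0.833
n32	n39	0.96
n32	n40	0.84
n33	n34	0.864
n33	n36	0.834
n33	n37	0.873
n33	n38	0.961
n33	n39	0.88
n33	n40	0.892
n34	n35	0.918
n34	n36	0.922
n34	n37	0.895
n34	n38	0.897
n34	n39	0.965
n34	n40	0.963
n35	n36	0.868
n35	n37	0.921
n35	n38	0.921
n35	n40	0.872
n35	n42	0.835
n36	n37	0.824
n36	n38	0.823
n36	n39	0.943
n36	n58	0.82
n37	n38	0.849
n37	n39	0.923
n37	n40	0.94
n37	n51	0.835
n41	n42	0.895
n41	n43	0.896
n41	n45	0.89
n41	n48	0.885
n41	n49	0.883
n41	n51	0.862
n41	n52	0.906
n41	n53	0.86
n41	n55	0.833
n41	n56	0.888
n41	n57	0.869
n41	n58	0.943
n41	n59	0.874
n41	n60	0.97
n42	n43	0.868
n42	n45	0.948
n42	n46	0.901
n42	n48	0.869
n42	n49	0.841
n42	n50	0.855
n42	n51	0.88
n42	n52	0.954
n42	n53	0.895
n42	n54	0.959
n42	n55	0.916
n42	n57	0.965
n42	n60	0.884
n43	n44	0.966
n43	n45	0.907
n43	n50	0.947
n43	n51	0.908
n43	n52	0.838
n43	n53	0.977
n43	n55	0.899
n43	n56	0.826
n43	n59	0.834
n43	n60	0.941
n44	n45	0.903
n44	n46	0.887
n44	n47	0.905
n44	n50	0.834
n44	n52	0.847
n44	n54	0.957
n44	n55	0.875
n45	n46	0.969
n45	n47	0.881
n45	n48	0.843
n45	n49	0.851
n45	n52	0.962
n45	n54	0.858
n45	n55	0.897
n45	n56	0.899
n45	n57	0.841
n45	n59	0.832
n45	n60	0.878
n46	n47	0.967
n46	n49	0.954
n46	n50	0.924
n46	n51	0.911
n46	n53	0.82
n46	n54	0.893
n46	n56	0.898
n46	n58	0.868
n46	n59	0.93
n47	n49	0.929
n47	n50	0.92
n47	n51	0.824
n47	n52	0.952
n47	n53	0.873
n47	n55	0.955
n47	n56	0.971
n47	n57	0.863
n47	n59	0.822
n47	n60	0.968
n48	n49	0.916
n48	n50	0.826
n48	n51	0.849
n48	n52	0.828
n48	n54	0.936
n48	n55	0.959
n48	n56	0.939
n48	n58	0.945
n49	n52	0.962
n49	n53	0.976
n49	n54	0.866
n49	n56	0.949
n49	n57	0.845
n49	n59	0.975
n50	n51	0.904
n50	n53	0.874
n50	n54	0.87
n50	n55	0.91
n50	n58	0.839
n51	n52	0.884
n51	n54	0.861
n51	n56	0.838
n51	n58	0.972
n51	n60	0.975
n52	n53	0.851
n52	n54	0.883
n52	n57	0.882
n52	n58	0.905
n52	n60	0.881
n53	n56	0.91
n53	n57	0.839
n53	n60	0.969
n54	n55	0.857
n54	n56	0.872
n54	n57	0.886
n54	n58	0.853
n54	n59	0.949
n55	n57	0.964
n55	n58	0.824
n55	n60	0.865
n56	n57	0.85
n56	n59	0.952
n57	n59	0.853
n58	n60	0.846
n59	n60	0.893
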