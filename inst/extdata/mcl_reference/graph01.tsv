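gene_a	gene_b	r
n01	n03	0.889
n01	n04	0.888
n01	n06	0.833
n01	n07	0.942
n01	n08	0.842
n01	n10	0.863
n01	n12	0.878
n01	n13	0.944
n01	n15	0.972
n01	n17	0.957
n01	n19	0.968
n01	n20	0.907
n01	n37	0.828
n02	n05	0.857
n02	n06	0.918
n02	n08	0.863
n02	n11	0.91
n02	n12	0.859
n02	n13	0.898
n02	n14	0.942
n02	n15	0.827
n02	n16	0.914
n03	n05	0.909
n03	n06	0.977
n03	n07	0.903
n03	n08	0.899
n03	n11	0.934
n03	n13	0.839
n03	n15	0.848
n03	n16	0.915
n03	n17	0.963
n03	n18	0.892
n03	n19	0.821
n03	n20	0.878
n04	n06	0.919
n04	n08	0.974
n04	n12	0.841
n04	n13	0.84
n04	n15	0.941
n04	n16	0.916
n04	n18	0.903
n04	n31	0.836
n04	n44	0.837
n05	n07	0.979
n05	n08	0.847
n05	n09	0.844
n05	n11	0.907
n05	n12	0.858
n05	n14	0.966
n05	n15	0.83
n05	n17	0.955
n05	n18	0.887
n05	n19	0.841
n05	n44	0.812
n06	n10	0.828
n06	n11	0.821
n06	n12	0.922
n06	n13	0.862
n06	n16	0.828
n06	n17	0.832
n06	n20	0.936
n07	n08	0.896
n07	n09	0.949
n07	n10	0.872
n07	n15	0.91
n07	n18	0.856
n07	n20	0.91
n08	n15	0.855
n08	n16	0.891
n08	n17	0.953
n08	n19	0.961
n08	n20	0.899
n08	n52	0.828
n09	n10	0.866
n09	n12	0.824
n09	n13	0.906
n09	n15	0.894
n09	n20	0.861
n09	n52	0.815
n10	n11	0.843
n10	n13	0.895
n10	n15	0.956
n10	n16	0.915
n10	n17	0.841
n10	n18	0.828
n10	n19	0.831
n11	n13	0.875
n11	n14	0.916
n11	n17	0.957
n11	n18	0.864
n11	n56	0.807
n12	n13	0.92
n12	n15	0.978
n12	n17	0.911
n12	n19	0.85
n12	n21	0.833
n12	n33	0.815
n13	n14	0.891
n13	n18	0.868
n13	n19	0.911
n13	n20	0.848
n13	n49	0.827
n14	n17	0.86
n14	n18	0.92
n14	n19	0.975
n14	n20	0.852
n14	n38	0.814
n15	n16	0.939
n15	n17	0.878
n15	n18	0.893
n15	n19	0.863
n15	n41	0.801
n15	n50	0.818
n16	n17	0.929
n16	n18	0.906
n16	n20	0.961
n16	n24	0.805
n16	n40	0.827
n17	n18	0.898
n17	n20	0.921
n18	n19	0.919
n18	n47	0.808
n19	n20	0.878
n20	n43	0.814
n20	n57	0.816
n21	n22	0.88
n21	n23	0.863
n21	n24	0.927
n21	n25	0.897
n21	n27	0.911
n21	n28	0.935
n21	n29	0.965
n21	n32	0.97
n21	n33	0.866
n21	n34	0.822
n21	n35	0.906
n21	n36	0.872
n21	n37	0.975
n21	n39	0.884
n21	n40	0.869
n21	n41	0.829
n22	n23	0.912
n22	n26	0.854
n22	n27	0.828
n22	n28	0.823
n22	n29	0.831
n22	n30	0.923
n22	n31	0.895
n22	n32	0.9
n22	n35	0.871
n22	n38	0.934
n22	n39	0.896
n22	n40	0.927
n23	n27	0.887
n23	n28	0.966
n23	n30	0.885
n23	n31	0.933
n23	n32	0.959
n23	n33	0.871
n23	n34	0.864
n23	n36	0.957
n23	n38	0.858
n24	n26	0.924
n24	n27	0.973
n24	n29	0.922
n24	n32	0.868
n24	n33	0.892
n24	n34	0.838
n24	n35	0.931
n24	n36	0.922
n24	n37	0.837
n24	n38	0.972
n24	n39	0.946
n24	n40	0.918
n25	n26	0.843
n25	n30	0.873
n25	n32	0.974
n25	n33	0.965
n25	n34	0.961
n25	n38	0.897
n25	n40	0.972
n26	n29	0.902
n26	n31	0.893
n26	n32	0.97
n26	n33	0.885
n26	n35	0.853
n26	n36	0.826
n26	n37	0.929
n26	n38	0.9
n26	n47	0.818
n27	n29	0.865
n27	n31	0.936
n27	n33	0.829
n27	n34	0.918
n27	n35	0.858
n27	n38	0.905
n28	n30	0.944
n28	n31	0.915
n28	n32	0.928
n28	n34	0.827
n28	n35	0.888
n28	n36	0.972
n28	n37	0.832
n28	n39	0.946
n28	n60	0.828
n29	n31	0.907
n29	n32	0.903
n29	n33	0.923
n29	n34	0.948
n29	n35	0.828
n29	n36	0.899
n29	n37	0.92
n29	n40	0.941
n30	n33	0.9
n30	n34	0.828
n30	n35	0.967
n30	n36	0.836
n30	n37	0.924
n30	n38	0.902
n30	n40	0.837
n31	n33	0.858
n31	n34	0.87
n31	n35	0.91
n31	n36	0.885
n32	n33	0.883
n32	n34	0.85
n32	n36	0.845
n32	n39	0.847
n32	n40	0.908
n32	n43	0.816
n33	n34	0.871
n33	n35	0.948
n33	n37	0.957
n33	n38	0.962
n33	n43	0.823
n34	n36	0.863
n34	n38	0.836
n34	n39	0.921
n34	n40	0.942
n35	n36	0.82
n35	n39	0.934
n35	n52	0.834
n36	n37	0.942
n36	n40	0.857
n37	n39	0.869
n37	n40	0.949
n39	n40	0.939
n40	n57	0.81
n41	n44	0.914
n41	n45	0.868
n41	n46	0.946
n41	n47	0.878
n41	n49	0.965
n41	n52	0.911
n41	n53	0.976
n41	n54	0.923
n42	n43	0.846
n42	n44	0.859
n42	n45	0.953
n42	n46	0.893
n42	n48	0.823
n42	n49	0.846
n42	n51	0.864
n42	n54	0.913
n42	n56	0.863
n42	n57	0.839
n42	n58	0.966
n43	n44	0.896
n43	n45	0.93
n43	n47	0.895
n43	n48	0.84
n43	n50	0.862
n43	n52	0.904
n43	n53	0.929
n43	n54	0.909
n43	n55	0.973
n43	n56	0.911
n43	n57	0.967
n43	n60	0.886
n44	n45	0.884
n44	n47	0.891
n44	n49	0.927
n44	n50	0.919
n44	n51	0.97
n44	n52	0.897
n44	n53	0.83
n44	n54	0.97
n44	n56	0.933
n44	n57	0.971
n44	n58	0.841
n44	n59	0.914
n45	n46	0.866
n45	n47	0.872
n45	n48	0.944
n45	n49	0.835
n45	n52	0.889
n45	n55	0.98
n45	n56	0.887
n46	n47	0.905
n46	n49	0.857
n46	n50	0.974
n46	n53	0.879
n46	n54	0.833
n46	n55	0.96
n46	n56	0.823
n46	n57	0.921
n46	n59	0.94
n47	n49	0.893
n47	n50	0.956
n47	n51	0.892
n47	n52	0.837
n47	n53	0.979
n47	n55	0.957
n47	n56	0.844
n47	n57	0.916
n47	n58	0.874
n47	n60	0.975
n48	n49	0.828
n48	n50	0.954
n48	n51	0.924
n48	n52	0.939
n48	n54	0.968
n48	n55	0.837
n48	n56	0.978
n48	n59	0.857
n48	n60	0.829
n49	n50	0.896
n49	n51	0.977
n49	n52	0.86
n49	n55	0.903
n49	n56	0.956
n49	n58	0.971
n49	n59	0.909
n49	n60	0.957
n50	n53	0.859
n50	n54	0.912
n50	n56	0.954
n50	n57	0.973
n50	n58	0.907
n51	n53	0.831
n51	n57	0.952
n51	n58	0.952
n51	n60	0.91
n52	n53	0.945
n52	n56	0.974
n52	n59	0.904
n53	n55	0.948
n53	n56	0.971
n53	n57	0.891
n53	n58	0.933
n53	n59	0.911
n54	n57	0.894
n54	n58	0.845
n54	n59	0.916
n55	n57	0.919
n55	n59	0.978
n55	n60	0.883
n56	n57	0.929
n56	n58	0.863
n57	n58	0.839
n57	n59	0.874
n57	n60	0.837
n58	n59	0.911
n58	n60	0.977
n59	n60	0.951
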