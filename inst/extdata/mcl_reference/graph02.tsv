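gene_a	gene_b	r
n01	n02	0.947
n01	n04	0.88
n01	n08	0.963
n01	n11	0.9
n01	n12	0.87
n01	n16	0.865
n01	n17	0.934
n01	n18	0.95
n01	n19	0.901
n01	n20	0.967
n02	n03	0.874
n02	n04	0.87
n02	n05	0.975
n02	n06	0.834
n02	n07	0.868
n02	n09	0.829
n02	n13	0.845
n02	n14	0.862
n02	n15	0.93
n02	n16	0.917
n02	n18	0.965
n02	n52	0.809
n03	n05	0.822
n03	n06	0.834
n03	n07	0.921
n03	n08	0.838
n03	n10	0.972
n03	n11	0.885
n03	n12	0.951
n03	n13	0.839
n03	n14	0.834
n03	n15	0.968
n03	n16	0.893
n03	n17	0.959
n03	n19	0.953
n03	n20	0.864
n04	n06	0.821
n04	n07	0.927
n04	n09	0.903
n04	n10	0.938
n04	n11	0.85
n04	n12	0.951
n04	n14	0.907
n04	n15	0.969
n04	n16	0.943
n04	n19	0.915
n04	n20	0.933
n04	n26	0.823
n05	n06	0.887
n05	n08	0.858
n05	n09	0.834
n05	n12	0.953
n05	n14	0.874
n05	n15	0.846
n05	n16	0.822
n05	n17	0.886
n05	n19	0.964
n06	n07	0.885
n06	n09	0.899
n06	n10	0.887
n06	n11	0.964
n06	n12	0.9
n06	n17	0.954
n06	n20	0.97
n06	n40	0.81
n06	n43	0.839
n07	n08	0.861
n07	n09	0.898
n07	n10	0.957
n07	n12	0.977
n07	n13	0.864
n07	n15	0.822
n07	n18	0.83
n07	n19	0.887
n07	n20	0.88
n07	n26	0.814
n08	n12	0.888
n08	n13	0.925
n08	n16	0.966
n08	n17	0.88
n08	n18	0.976
n08	n19	0.967
n08	n20	0.847
n08	n39	0.839
n09	n12	0.852
n09	n13	0.853
n09	n15	0.887
n09	n17	0.884
n09	n19	0.872
n09	n20	0.881
n09	n39	0.811
n10	n12	0.906
n10	n14	0.824
n10	n15	0.832
n10	n17	0.825
n10	n18	0.963
n10	n20	0.856
n11	n12	0.958
n11	n13	0.935
n11	n14	0.919
n11	n16	0.883
n11	n17	0.866
n11	n20	0.928
n12	n14	0.977
n12	n16	0.823
n12	n17	0.889
n12	n18	0.858
n12	n20	0.956
n12	n43	0.822
n13	n14	0.889
n13	n16	0.903
n13	n17	0.903
n13	n18	0.957
n13	n19	0.888
n13	n20	0.841
n14	n18	0.895
n14	n19	0.888
n14	n21	0.84
n15	n16	0.894
n15	n17	0.877
n16	n18	0.883
n16	n33	0.832
n17	n19	0.874
n17	n20	0.865
n18	n19	0.89
n18	n29	0.82
n18	n38	0.808
n19	n20	0.865
n19	n50	0.82
n20	n54	0.836
n21	n24	0.923
n21	n26	0.849
n21	n27	0.859
n21	n28	0.944
n21	n29	0.843
n21	n32	0.947
n21	n35	0.888
n21	n36	0.882
n21	n38	0.964
n21	n39	0.95
n21	n40	0.845
n22	n24	0.961
n22	n26	0.974
n22	n27	0.877
n22	n28	0.852
n22	n29	0.83
n22	n31	0.968
n22	n32	0.95
n22	n37	0.863
n22	n38	0.868
n22	n39	0.895
n23	n24	0.945
n23	n25	0.963
n23	n26	0.893
n23	n27	0.892
n23	n28	0.83
n23	n31	0.894
n23	n32	0.857
n23	n33	0.874
n23	n34	0.861
n23	n37	0.913
n23	n39	0.842
n23	n40	0.934
n24	n26	0.932
n24	n29	0.975
n24	n30	0.886
n24	n31	0.829
n24	n33	0.885
n24	n34	0.873
n24	n38	0.907
n24	n39	0.919
n24	n40	0.853
n24	n50	0.822
n25	n28	0.964
n25	n32	0.943
n25	n33	0.859
n25	n34	0.973
n25	n36	0.888
n25	n37	0.95
n25	n38	0.979
n25	n39	0.834
n25	n40	0.867
n26	n27	0.851
n26	n28	0.969
n26	n29	0.925
n26	n30	0.861
n26	n31	0.925
n26	n32	0.841
n26	n33	0.865
n26	n34	0.835
n26	n37	0.902
n26	n39	0.969
n27	n29	0.941
n27	n31	0.951
n27	n32	0.827
n27	n33	0.821
n27	n35	0.85
n27	n36	0.897
n27	n37	0.868
n27	n38	0.889
n28	n29	0.914
n28	n30	0.907
n28	n31	0.911
n28	n32	0.824
n28	n33	0.962
n28	n34	0.978
n28	n35	0.918
n28	n36	0.893
n28	n37	0.942
n28	n38	0.934
n29	n30	0.957
n29	n31	0.92
n29	n32	0.884
n29	n33	0.973
n29	n36	0.91
n29	n37	0.832
n29	n38	0.832
n29	n40	0.973
n30	n31	0.829
n30	n32	0.927
n30	n35	0.892
n30	n36	0.827
n30	n38	0.888
n30	n39	0.883
n30	n40	0.946
n31	n32	0.845
n31	n34	0.839
n31	n35	0.948
n31	n37	0.895
n31	n38	0.895
n31	n39	0.874
n31	n40	0.96
n32	n33	0.962
n32	n34	0.918
n32	n35	0.865
n32	n36	0.951
n32	n39	0.975
n32	n40	0.925
n33	n36	0.911
n33	n37	0.98
n33	n38	0.892
n33	n40	0.94
n33	n56	0.807
n34	n36	0.837
n34	n37	0.956
n34	n39	0.865
n34	n40	0.834
n35	n36	0.96
n35	n37	0.94
n35	n38	0.909
n35	n39	0.867
n36	n38	0.854
n36	n39	0.941
n36	n40	0.843
n36	n57	0.803
n37	n38	0.873
n37	n39	0.93
n37	n40	0.884
n37	n51	0.815
n38	n40	0.821
n39	n40	0.945
n39	n54	0.833
n41	n42	0.953
n41	n43	0.971
n41	n46	0.934
n41	n50	0.952
n41	n52	0.923
n41	n53	0.89
n41	n54	0.83
n41	n55	0.857
n41	n56	0.937
n41	n57	0.883
n41	n60	0.898
n42	n43	0.858
n42	n45	0.881
n42	n46	0.923
n42	n47	0.87
n42	n48	0.911
n42	n49	0.921
n42	n50	0.956
n42	n53	0.858
n42	n58	0.976
n42	n59	0.826
n42	n60	0.874
n43	n44	0.97
n43	n46	0.952
n43	n47	0.943
n43	n48	0.977
n43	n49	0.902
n43	n50	0.868
n43	n51	0.832
n43	n52	0.87
n43	n53	0.932
n43	n54	0.939
n43	n57	0.864
n43	n60	0.967
n44	n47	0.84
n44	n49	0.968
n44	n50	0.944
n44	n51	0.865
n44	n52	0.861
n44	n53	0.882
n44	n54	0.976
n44	n55	0.826
n44	n58	0.944
n44	n59	0.84
n44	n60	0.958
n45	n46	0.91
n45	n47	0.856
n45	n48	0.855
n45	n49	0.913
n45	n50	0.946
n45	n52	0.863
n45	n53	0.872
n45	n54	0.842
n45	n56	0.974
n45	n59	0.883
n45	n60	0.9
n46	n47	0.973
n46	n48	0.97
n46	n54	0.948
n46	n56	0.882
n46	n59	0.855
n47	n50	0.889
n47	n51	0.961
n47	n52	0.891
n47	n54	0.877
n47	n60	0.883
n48	n49	0.826
n48	n51	0.895
n48	n52	0.87
n48	n53	0.836
n48	n55	0.829
n48	n58	0.896
n48	n59	0.837
n49	n50	0.847
n49	n51	0.893
n49	n52	0.948
n49	n53	0.896
n49	n54	0.948
n49	n59	0.952
n49	n60	0.898
n50	n51	0.892
n50	n52	0.936
n50	n55	0.98
n50	n56	0.862
n50	n59	0.879
n51	n52	0.972
n51	n53	0.965
n51	n55	0.976
n51	n56	0.913
n51	n57	0.83
n51	n58	0.874
n51	n59	0.871
n51	n60	0.877
n52	n53	0.943
n52	n55	0.961
n52	n57	0.822
n52	n58	0.848
n52	n59	0.823
n52	n60	0.863
n53	n55	0.902
n53	n57	0.87
n53	n58	0.836
n53	n59	0.979
n54	n56	0.938
n54	n57	0.904
n54	n60	0.836
n55	n56	0.838
n55	n58	0.895
n55	n60	0.835
n56	n58	0.834
n56	n60	0.963
n57	n60	0.862
n58	n60	0.821
n59	n60	0.838
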