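gene_a	gene_b	r
n01	n02	0.859
n01	n05	0.966
n01	n06	0.88
n01	n07	0.888
n01	n08	0.878
n01	n09	0.845
n01	n11	0.85
n01	n14	0.825
n01	n17	0.91
n01	n19	0.879
n02	n03	0.907
n02	n05	0.958
n02	n07	0.863
n02	n09	0.84
n02	n10	0.95
n02	n13	0.843
n02	n15	0.906
n02	n16	0.971
n02	n38	0.831
n03	n07	0.89
n03	n10	0.886
n03	n12	0.886
n03	n15	0.95
n03	n18	0.903
n03	n19	0.908
n03	n41	0.806
n04	n05	0.917
n04	n06	0.929
n04	n07	0.822
n04	n09	0.821
n04	n11	0.893
n04	n12	0.866
n04	n13	0.95
n04	n15	0.932
n04	n16	0.836
n04	n17	0.911
n04	n18	0.963
n04	n22	0.819
n04	n30	0.801
n05	n10	0.834
n05	n11	0.891
n05	n12	0.891
n05	n13	0.856
n05	n16	0.961
n05	n18	0.912
n05	n19	0.846
n05	n20	0.856
n06	n07	0.88
n06	n08	0.885
n06	n09	0.832
n06	n10	0.931
n06	n13	0.932
n06	n14	0.905
n06	n15	0.915
n06	n60	0.817
n07	n08	0.873
n07	n09	0.855
n07	n11	0.96
n07	n12	0.946
n07	n15	0.831
n07	n16	0.948
n07	n17	0.831
n07	n20	0.914
n08	n09	0.897
n08	n10	0.847
n08	n11	0.893
n08	n12	0.87
n08	n15	0.88
n08	n16	0.935
n08	n18	0.842
n08	n19	0.871
n08	n20	0.87
n08	n34	0.821
n09	n10	0.848
n09	n11	0.936
n09	n12	0.891
n09	n16	0.838
n09	n17	0.934
n09	n20	0.827
n10	n14	0.859
n10	n15	0.954
n10	n19	0.826
n10	n20	0.954
n10	n45	0.833
n10	n52	0.814
n11	n13	0.92
n11	n14	0.889
n11	n15	0.92
n11	n16	0.925
n11	n17	0.958
n11	n18	0.822
n11	n20	0.905
n12	n13	0.875
n12	n15	0.964
n12	n17	0.858
n12	n18	0.885
n12	n19	0.96
n12	n20	0.949
n12	n43	0.8
n13	n14	0.924
n13	n15	0.838
n13	n17	0.879
n13	n18	0.904
n13	n19	0.84
n14	n15	0.853
n14	n16	0.958
n14	n17	0.853
n14	n18	0.86
n14	n19	0.975
n14	n20	0.875
n15	n18	0.871
n15	n50	0.815
n16	n17	0.944
n16	n19	0.934
n16	n20	0.886
n16	n27	0.811
n17	n18	0.896
n17	n20	0.891
n18	n19	0.965
n18	n49	0.836
n19	n20	0.932
n19	n35	0.834
n21	n23	0.907
n21	n25	0.902
n21	n26	0.919
n21	n28	0.974
n21	n29	0.903
n21	n30	0.947
n21	n32	0.951
n21	n33	0.873
n21	n34	0.948
n21	n35	0.872
n21	n36	0.93
n21	n38	0.942
n21	n40	0.951
n21	n53	0.813
n22	n23	0.902
n22	n24	0.97
n22	n26	0.927
n22	n28	0.821
n22	n29	0.836
n22	n30	0.961
n22	n31	0.83
n22	n32	0.888
n22	n33	0.901
n22	n34	0.851
n22	n35	0.914
n22	n36	0.978
n22	n37	0.873
n22	n39	0.911
n22	n40	0.889
n23	n24	0.906
n23	n27	0.856
n23	n30	0.921
n23	n31	0.899
n23	n33	0.896
n23	n35	0.967
n23	n36	0.954
n23	n37	0.979
n23	n39	0.837
n23	n43	0.815
n24	n25	0.948
n24	n27	0.877
n24	n28	0.925
n24	n29	0.897
n24	n30	0.848
n24	n31	0.847
n24	n33	0.837
n24	n34	0.904
n24	n38	0.936
n24	n39	0.938
n24	n40	0.944
n24	n59	0.824
n25	n28	0.87
n25	n29	0.947
n25	n31	0.966
n25	n34	0.937
n25	n35	0.856
n25	n36	0.866
n25	n40	0.884
n26	n27	0.937
n26	n29	0.891
n26	n32	0.822
n26	n33	0.899
n26	n35	0.914
n26	n36	0.884
n26	n38	0.93
n26	n39	0.86
n27	n28	0.875
n27	n29	0.882
n27	n30	0.962
n27	n31	0.832
n27	n32	0.838
n27	n33	0.851
n27	n34	0.867
n27	n35	0.93
n27	n36	0.88
n27	n37	0.865
n27	n39	0.831
n27	n40	0.974
n27	n49	0.833
n28	n29	0.963
n28	n30	0.97
n28	n34	0.914
n28	n35	0.894
n28	n37	0.866
n28	n38	0.945
n28	n48	0.806
n29	n33	0.864
n29	n34	0.87
n29	n35	0.933
n29	n36	0.843
n29	n37	0.97
n29	n38	0.968
n30	n32	0.877
n30	n34	0.896
n30	n35	0.884
n30	n36	0.849
n30	n37	0.885
n30	n38	0.904
n31	n33	0.844
n31	n36	0.961
n31	n39	0.828
n31	n40	0.941
n32	n33	0.942
n32	n34	0.884
n32	n36	0.947
n32	n38	0.862
n32	n39	0.947
n33	n36	0.929
n33	n38	0.968
n33	n40	0.893
n34	n37	0.825
n34	n38	0.829
n34	n40	0.872
n35	n36	0.921
n35	n39	0.892
n36	n37	0.881
n36	n39	0.892
n36	n40	0.833
n37	n38	0.847
n37	n39	0.941
n37	n40	0.836
n38	n40	0.904
n38	n55	0.818
n41	n42	0.911
n41	n43	0.836
n41	n44	0.897
n41	n46	0.877
n41	n47	0.86
n41	n48	0.873
n41	n49	0.866
n41	n51	0.913
n41	n53	0.919
n41	n54	0.936
n41	n56	0.893
n41	n57	0.974
n41	n58	0.856
n41	n59	0.961
n42	n44	0.888
n42	n45	0.979
n42	n47	0.855
n42	n48	0.954
n42	n49	0.931
n42	n51	0.978
n42	n55	0.905
n42	n58	0.877
n42	n59	0.835
n42	n60	0.98
n43	n44	0.974
n43	n50	0.83
n43	n51	0.84
n43	n53	0.93
n43	n54	0.973
n43	n55	0.955
n43	n56	0.882
n43	n59	0.866
n43	n60	0.831
n44	n46	0.968
n44	n47	0.96
n44	n48	0.916
n44	n50	0.849
n44	n54	0.858
n44	n55	0.873
n44	n57	0.872
n44	n58	0.907
n45	n48	0.873
n45	n49	0.883
n45	n50	0.886
n45	n51	0.897
n45	n53	0.915
n45	n56	0.952
n45	n57	0.915
n45	n59	0.908
n45	n60	0.903
n46	n47	0.932
n46	n49	0.94
n46	n50	0.951
n46	n51	0.936
n46	n52	0.884
n46	n53	0.891
n46	n54	0.855
n46	n55	0.955
n46	n56	0.845
n47	n49	0.836
n47	n50	0.931
n47	n51	0.974
n47	n52	0.91
n47	n55	0.964
n47	n58	0.948
n47	n60	0.869
n48	n50	0.88
n48	n54	0.925
n48	n57	0.843
n48	n58	0.836
n48	n60	0.891
n49	n50	0.907
n49	n52	0.86
n49	n53	0.846
n49	n55	0.9
n49	n56	0.872
n49	n57	0.935
n49	n59	0.945
n50	n51	0.826
n50	n52	0.923
n50	n53	0.826
n50	n56	0.827
n50	n57	0.928
n50	n58	0.919
n51	n52	0.924
n51	n53	0.836
n51	n54	0.97
n51	n55	0.962
n51	n56	0.836
n51	n57	0.958
n51	n58	0.962
n51	n60	0.948
n52	n54	0.978
n52	n56	0.857
n52	n57	0.953
n53	n55	0.831
n53	n56	0.879
n53	n58	0.936
n54	n56	0.911
n54	n60	0.897
n55	n59	0.974
n56	n57	0.935
n56	n60	0.841
n57	n59	0.907
n57	n60	0.849
n58	n59	0.823
n59	n60	0.832
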