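gene_a	gene_b	r
n01	n03	0.918
n01	n04	0.964
n01	n05	0.901
n01	n07	0.918
n01	n09	0.963
n01	n10	0.896
n01	n12	0.824
n01	n14	0.959
n01	n15	0.935
n01	n17	0.932
n01	n19	0.869
n01	n20	0.906
n02	n03	0.959
n02	n04	0.872
n02	n05	0.935
n02	n08	0.917
n02	n09	0.905
n02	n10	0.964
n02	n11	0.893
n02	n12	0.867
n02	n14	0.927
n02	n17	0.953
n03	n05	0.915
n03	n09	0.908
n03	n10	0.97
n03	n11	0.972
n03	n15	0.971
n03	n17	0.965
n03	n18	0.901
n03	n19	0.832
n03	n20	0.948
n03	n49	0.835
n04	n05	0.926
n04	n06	0.881
n04	n07	0.895
n04	n08	0.856
n04	n10	0.867
n04	n12	0.827
n04	n13	0.913
n04	n14	0.871
n04	n19	0.944
n04	n20	0.854
n05	n07	0.849
n05	n09	0.98
n05	n10	0.828
n05	n12	0.88
n05	n13	0.845
n05	n15	0.849
n05	n18	0.917
n05	n20	0.863
n05	n49	0.827
n06	n08	0.93
n06	n11	0.949
n06	n12	0.972
n06	n13	0.859
n06	n14	0.856
n06	n15	0.869
n06	n17	0.868
n06	n19	0.827
n07	n08	0.888
n07	n11	0.916
n07	n12	0.967
n07	n13	0.965
n07	n14	0.847
n07	n15	0.887
n07	n16	0.82
n07	n18	0.955
n07	n20	0.925
n08	n10	0.928
n08	n11	0.969
n08	n12	0.855
n08	n14	0.956
n08	n15	0.895
n08	n18	0.907
n09	n10	0.926
n09	n11	0.955
n09	n12	0.924
n09	n13	0.951
n09	n14	0.83
n09	n16	0.98
n09	n17	0.979
n09	n18	0.851
n09	n19	0.85
n09	n20	0.841
n09	n33	0.807
n10	n11	0.954
n10	n12	0.825
n10	n14	0.89
n10	n17	0.83
n10	n18	0.898
n10	n19	0.939
n11	n12	0.874
n11	n13	0.928
n11	n16	0.932
n11	n18	0.898
n12	n13	0.877
n12	n14	0.908
n12	n15	0.933
n12	n16	0.963
n12	n20	0.956
n13	n14	0.838
n13	n17	0.867
n13	n19	0.854
n13	n53	0.819
n14	n18	0.889
n14	n20	0.844
n14	n21	0.814
n15	n19	0.971
n16	n17	0.972
n16	n19	0.887
n16	n20	0.937
n16	n27	0.839
n16	n29	0.836
n17	n18	0.929
n17	n19	0.946
n17	n38	0.813
n19	n20	0.884
n20	n37	0.823
n21	n23	0.892
n21	n26	0.959
n21	n27	0.897
n21	n34	0.85
n21	n35	0.951
n21	n37	0.881
n21	n38	0.874
n21	n40	0.847
n22	n24	0.907
n22	n25	0.873
n22	n27	0.852
n22	n29	0.918
n22	n30	0.835
n22	n31	0.959
n22	n32	0.933
n22	n33	0.945
n22	n34	0.895
n22	n35	0.845
n22	n36	0.835
n22	n37	0.9
n22	n38	0.862
n22	n39	0.907
n22	n52	0.823
n23	n24	0.939
n23	n26	0.944
n23	n28	0.859
n23	n29	0.961
n23	n35	0.969
n23	n37	0.874
n23	n38	0.963
n23	n40	0.842
n24	n26	0.829
n24	n31	0.919
n24	n33	0.879
n24	n34	0.909
n24	n35	0.865
n24	n37	0.821
n24	n39	0.919
n25	n26	0.884
n25	n27	0.826
n25	n30	0.912
n25	n32	0.889
n25	n34	0.932
n25	n35	0.846
n25	n36	0.821
n25	n38	0.821
n25	n39	0.912
n26	n27	0.829
n26	n28	0.976
n26	n30	0.955
n26	n33	0.868
n26	n34	0.876
n26	n35	0.843
n26	n36	0.966
n26	n37	0.945
n26	n38	0.91
n26	n39	0.903
n26	n40	0.866
n27	n28	0.931
n27	n29	0.977
n27	n30	0.908
n27	n31	0.833
n27	n32	0.847
n27	n34	0.927
n27	n35	0.825
n27	n36	0.971
n27	n37	0.866
n27	n39	0.889
n27	n43	0.83
n28	n31	0.978
n28	n32	0.925
n28	n33	0.924
n28	n34	0.964
n28	n35	0.851
n28	n36	0.889
n28	n40	0.931
n28	n48	0.805
n29	n32	0.84
n29	n33	0.94
n29	n36	0.925
n29	n37	0.979
n29	n38	0.911
n29	n39	0.915
n29	n40	0.878
n30	n35	0.849
n30	n39	0.848
n30	n40	0.971
n30	n50	0.82
n31	n32	0.912
n31	n34	0.919
n31	n36	0.92
n31	n39	0.915
n32	n34	0.84
n32	n37	0.848
n32	n39	0.87
n32	n40	0.906
n32	n55	0.813
n33	n34	0.869
n33	n36	0.862
n33	n37	0.913
n33	n38	0.964
n34	n36	0.933
n34	n37	0.836
n34	n39	0.923
n34	n40	0.84
n35	n36	0.911
n35	n37	0.822
n35	n38	0.885
n35	n39	0.924
n36	n37	0.955
n36	n39	0.926
n37	n38	0.83
n37	n39	0.855
n37	n40	0.934
n37	n45	0.816
n40	n48	0.813
n41	n46	0.899
n41	n49	0.915
n41	n51	0.93
n41	n52	0.829
n41	n53	0.928
n41	n54	0.933
n41	n59	0.836
n42	n43	0.894
n42	n45	0.95
n42	n46	0.854
n42	n47	0.918
n42	n48	0.962
n42	n49	0.9
n42	n50	0.823
n42	n51	0.913
n42	n52	0.882
n42	n53	0.927
n42	n54	0.904
n42	n56	0.932
n42	n57	0.97
n42	n58	0.894
n42	n59	0.965
n43	n44	0.876
n43	n45	0.827
n43	n46	0.939
n43	n48	0.92
n43	n49	0.955
n43	n50	0.87
n43	n51	0.968
n43	n54	0.83
n43	n56	0.896
n43	n57	0.886
n43	n59	0.882
n44	n48	0.889
n44	n49	0.894
n44	n50	0.855
n44	n51	0.938
n44	n52	0.964
n44	n54	0.918
n44	n55	0.869
n44	n56	0.824
n44	n57	0.862
n44	n60	0.829
n45	n46	0.941
n45	n48	0.963
n45	n50	0.908
n45	n52	0.859
n45	n53	0.899
n45	n54	0.826
n45	n58	0.946
n45	n59	0.928
n46	n47	0.949
n46	n49	0.836
n46	n52	0.826
n46	n54	0.933
n46	n55	0.964
n46	n56	0.833
n46	n57	0.971
n47	n48	0.878
n47	n49	0.944
n47	n54	0.923
n47	n56	0.861
n47	n57	0.826
n47	n58	0.848
n47	n59	0.914
n47	n60	0.82
n48	n49	0.845
n48	n50	0.864
n48	n51	0.822
n48	n54	0.927
n48	n56	0.911
n48	n57	0.841
n48	n58	0.94
n48	n59	0.871
n49	n53	0.863
n49	n54	0.945
n49	n55	0.867
n49	n56	0.974
n50	n53	0.949
n50	n56	0.979
n50	n57	0.885
n50	n58	0.85
n50	n60	0.96
n51	n52	0.868
n51	n53	0.92
n51	n54	0.872
n51	n57	0.898
n51	n58	0.896
n51	n59	0.869
n52	n55	0.895
n52	n57	0.844
n52	n58	0.847
n53	n57	0.903
n53	n58	0.894
n54	n57	0.844
n54	n58	0.822
n55	n56	0.975
n55	n57	0.97
n55	n58	0.964
n55	n59	0.839
n55	n60	0.859
n56	n57	0.898
n56	n59	0.947
n56	n60	0.852
n58	n59	0.896
n59	n60	0.917
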