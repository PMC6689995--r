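gene_a	gene_b	r
n01	n02	0.97
n01	n03	0.963
n01	n09	0.946
n01	n13	0.935
n01	n14	0.887
n01	n18	0.969
n01	n19	0.945
n02	n03	0.97
n02	n04	0.968
n02	n05	0.974
n02	n06	0.968
n02	n07	0.848
n02	n08	0.884
n02	n09	0.977
n02	n10	0.868
n02	n11	0.918
n02	n13	0.92
n02	n14	0.892
n02	n15	0.969
n02	n18	0.945
n02	n19	0.867
n02	n20	0.866
n03	n04	0.886
n03	n05	0.843
n03	n06	0.944
n03	n07	0.968
n03	n09	0.889
n03	n10	0.873
n03	n11	0.82
n03	n12	0.86
n03	n15	0.856
n03	n16	0.943
n03	n17	0.93
n03	n19	0.97
n03	n20	0.839
n04	n05	0.953
n04	n06	0.923
n04	n07	0.878
n04	n08	0.83
n04	n10	0.84
n04	n11	0.865
n04	n13	0.895
n04	n17	0.895
n04	n18	0.94
n04	n31	0.838
n05	n06	0.887
n05	n07	0.96
n05	n08	0.851
n05	n09	0.879
n05	n11	0.84
n05	n14	0.851
n05	n17	0.919
n05	n18	0.876
n05	n19	0.859
n05	n39	0.832
n06	n07	0.849
n06	n08	0.947
n06	n10	0.96
n06	n13	0.957
n06	n14	0.912
n06	n15	0.833
n06	n17	0.94
n07	n09	0.933
n07	n10	0.962
n07	n11	0.822
n07	n12	0.891
n07	n13	0.898
n07	n14	0.946
n07	n15	0.954
n07	n16	0.855
n07	n17	0.858
n07	n18	0.861
n07	n19	0.968
n07	n20	0.932
n08	n09	0.936
n08	n10	0.979
n08	n11	0.873
n08	n12	0.932
n08	n17	0.923
n08	n18	0.871
n09	n12	0.911
n09	n13	0.905
n09	n16	0.859
n09	n17	0.837
n09	n20	0.821
n09	n28	0.806
n09	n33	0.803
n09	n36	0.807
n10	n12	0.823
n10	n15	0.877
n10	n16	0.841
n10	n19	0.942
n10	n20	0.941
n10	n29	0.806
n10	n49	0.829
n11	n12	0.867
n11	n13	0.887
n11	n14	0.828
n11	n15	0.968
n11	n16	0.94
n11	n17	0.916
n11	n18	0.956
n11	n19	0.906
n11	n20	0.842
n11	n56	0.826
n12	n14	0.886
n12	n16	0.896
n12	n18	0.894
n12	n20	0.9
n12	n24	0.824
n13	n15	0.839
n13	n16	0.974
n13	n17	0.969
n13	n22	0.821
n13	n23	0.831
n13	n43	0.833
n14	n15	0.972
n14	n18	0.849
n14	n19	0.932
n14	n20	0.926
n15	n17	0.895
n15	n18	0.857
n15	n20	0.882
n16	n17	0.878
n16	n19	0.915
n16	n31	0.805
n17	n19	0.866
n17	n20	0.867
n17	n30	0.824
n18	n20	0.911
n19	n20	0.96
n21	n23	0.94
n21	n24	0.887
n21	n25	0.959
n21	n27	0.948
n21	n31	0.874
n21	n34	0.924
n21	n35	0.963
n21	n38	0.931
n21	n39	0.84
n21	n48	0.813
n22	n23	0.907
n22	n24	0.87
n22	n27	0.932
n22	n28	0.856
n22	n29	0.899
n22	n31	0.899
n22	n33	0.922
n22	n34	0.933
n22	n36	0.847
n22	n40	0.937
n23	n25	0.958
n23	n28	0.924
n23	n29	0.924
n23	n30	0.851
n23	n31	0.909
n23	n34	0.829
n23	n35	0.951
n23	n36	0.937
n23	n37	0.874
n23	n38	0.836
n23	n39	0.835
n23	n40	0.887
n24	n27	0.882
n24	n28	0.832
n24	n30	0.972
n24	n31	0.903
n24	n32	0.959
n24	n34	0.959
n24	n35	0.844
n24	n36	0.975
n24	n37	0.958
n24	n38	0.829
n24	n39	0.855
n24	n41	0.824
n24	n49	0.815
n25	n27	0.892
n25	n28	0.9
n25	n29	0.919
n25	n30	0.936
n25	n31	0.919
n25	n32	0.844
n25	n33	0.904
n25	n36	0.899
n25	n40	0.836
n26	n28	0.841
n26	n31	0.967
n26	n32	0.822
n26	n34	0.82
n26	n35	0.898
n26	n36	0.975
n27	n28	0.915
n27	n30	0.905
n27	n32	0.978
n27	n34	0.97
n27	n35	0.851
n27	n39	0.861
n28	n30	0.948
n28	n31	0.881
n28	n32	0.932
n28	n34	0.906
n28	n36	0.866
n28	n38	0.922
n28	n39	0.881
n28	n40	0.918
n28	n44	0.826
n28	n57	0.835
n29	n30	0.925
n29	n31	0.871
n29	n32	0.877
n29	n36	0.892
n29	n37	0.874
n29	n38	0.92
n29	n39	0.862
n29	n40	0.962
n30	n31	0.89
n30	n34	0.93
n30	n35	0.88
n30	n36	0.924
n30	n38	0.859
n30	n39	0.931
n30	n40	0.954
n31	n35	0.906
n31	n36	0.91
n31	n37	0.947
n31	n39	0.945
n31	n40	0.927
n32	n34	0.976
n32	n35	0.871
n32	n38	0.879
n32	n39	0.885
n33	n35	0.882
n33	n36	0.979
n33	n37	0.935
n33	n38	0.866
n33	n40	0.839
n34	n35	0.927
n34	n36	0.977
n34	n37	0.973
n34	n39	0.884
n34	n40	0.868
n35	n36	0.885
n35	n38	0.941
n35	n40	0.858
n35	n50	0.839
n36	n37	0.956
n36	n38	0.841
n36	n39	0.934
n37	n38	0.923
n37	n40	0.909
n37	n49	0.807
n38	n40	0.965
n39	n40	0.878
n41	n43	0.839
n41	n44	0.896
n41	n45	0.917
n41	n46	0.904
n41	n47	0.919
n41	n48	0.83
n41	n49	0.96
n41	n52	0.92
n41	n53	0.97
n41	n56	0.978
n41	n58	0.945
n42	n45	0.959
n42	n46	0.97
n42	n47	0.875
n42	n48	0.89
n42	n51	0.888
n42	n55	0.893
n42	n58	0.97
n42	n60	0.842
n43	n44	0.909
n43	n46	0.942
n43	n47	0.955
n43	n49	0.968
n43	n53	0.893
n43	n55	0.833
n43	n57	0.941
n44	n48	0.912
n44	n49	0.908
n44	n51	0.949
n44	n52	0.851
n44	n53	0.912
n45	n46	0.832
n45	n47	0.958
n45	n48	0.925
n45	n49	0.924
n45	n50	0.883
n45	n52	0.892
n45	n53	0.911
n45	n54	0.863
n45	n56	0.839
n45	n57	0.93
n45	n58	0.909
n46	n48	0.87
n46	n49	0.951
n46	n50	0.979
n46	n52	0.823
n46	n53	0.849
n46	n54	0.904
n46	n56	0.925
n46	n58	0.979
n46	n59	0.943
n46	n60	0.872
n47	n48	0.847
n47	n49	0.886
n47	n51	0.883
n47	n54	0.978
n47	n56	0.877
n47	n57	0.879
n47	n58	0.905
n48	n49	0.974
n48	n50	0.914
n48	n51	0.971
n48	n53	0.847
n48	n54	0.884
n48	n57	0.911
n49	n50	0.853
n49	n52	0.942
n49	n53	0.824
n49	n54	0.936
n49	n55	0.864
n49	n56	0.868
n49	n60	0.868
n50	n53	0.838
n50	n58	0.923
n50	n59	0.834
n50	n60	0.962
n51	n53	0.941
n51	n54	0.92
n51	n56	0.866
n51	n58	0.943
n51	n59	0.898
n51	n60	0.907
n52	n53	0.822
n52	n55	0.917
n52	n57	0.888
n52	n60	0.954
n53	n54	0.901
n53	n58	0.952
n53	n59	0.892
n53	n60	0.936
n54	n57	0.968
n54	n60	0.953
n55	n56	0.87
n55	n59	0.933
n55	n60	0.965
n56	n59	0.975
n57	n58	0.854
n57	n59	0.903
n59	n60	0.933
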