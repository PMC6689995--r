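gene_a	gene_b	r
n01	n02	0.881
n01	n03	0.864
n01	n04	0.947
n01	n07	0.928
n01	n08	0.915
n01	n12	0.942
n01	n13	0.941
n01	n14	0.915
n01	n16	0.887
n01	n17	0.904
n01	n18	0.854
n01	n20	0.962
n01	n39	0.815
n02	n08	0.842
n02	n12	0.888
n02	n15	0.962
n02	n17	0.833
n02	n19	0.9
n02	n20	0.872
n03	n04	0.828
n03	n05	0.966
n03	n06	0.836
n03	n07	0.961
n03	n09	0.839
n03	n14	0.968
n03	n16	0.92
n03	n17	0.871
n03	n18	0.871
n03	n19	0.843
n04	n05	0.932
n04	n06	0.894
n04	n08	0.929
n04	n13	0.925
n04	n15	0.905
n04	n17	0.888
n04	n19	0.978
n04	n20	0.857
n05	n06	0.919
n05	n08	0.973
n05	n09	0.918
n05	n11	0.908
n05	n12	0.86
n05	n15	0.977
n05	n16	0.869
n05	n17	0.936
n05	n18	0.831
n05	n19	0.842
n05	n44	0.824
n06	n11	0.948
n06	n12	0.912
n06	n13	0.96
n06	n17	0.904
n06	n18	0.93
n06	n20	0.949
n06	n47	0.809
n07	n08	0.829
n07	n09	0.892
n07	n12	0.943
n07	n14	0.91
n07	n15	0.841
n07	n18	0.908
n07	n20	0.98
n08	n12	0.971
n08	n13	0.952
n08	n14	0.888
n08	n16	0.937
n08	n17	0.907
n08	n19	0.942
n09	n11	0.979
n09	n14	0.885
n09	n16	0.839
n09	n17	0.926
n09	n19	0.901
n09	n20	0.853
n10	n12	0.909
n10	n14	0.842
n10	n15	0.847
n10	n16	0.927
n10	n18	0.933
n10	n19	0.89
n10	n20	0.956
n10	n45	0.84
n11	n12	0.829
n11	n13	0.978
n11	n16	0.888
n11	n20	0.969
n12	n13	0.821
n12	n14	0.882
n12	n16	0.895
n12	n17	0.865
n12	n19	0.966
n13	n14	0.852
n13	n15	0.878
n13	n20	0.94
n14	n15	0.882
n14	n17	0.949
n14	n18	0.953
n14	n25	0.816
n14	n58	0.828
n15	n16	0.95
n15	n17	0.842
n15	n18	0.847
n15	n19	0.83
n15	n40	0.827
n16	n18	0.98
n16	n19	0.959
n16	n60	0.814
n17	n18	0.94
n17	n19	0.969
n19	n20	0.869
n20	n40	0.839
n20	n44	0.813
n21	n22	0.972
n21	n24	0.872
n21	n25	0.873
n21	n26	0.929
n21	n27	0.979
n21	n29	0.882
n21	n31	0.973
n21	n33	0.931
n21	n34	0.955
n21	n37	0.912
n21	n38	0.924
n21	n40	0.95
n21	n47	0.834
n22	n24	0.914
n22	n25	0.965
n22	n27	0.917
n22	n28	0.957
n22	n29	0.843
n22	n31	0.866
n22	n32	0.843
n22	n33	0.863
n22	n35	0.942
n22	n36	0.924
n22	n37	0.84
n22	n39	0.877
n22	n40	0.86
n22	n58	0.826
n23	n25	0.836
n23	n28	0.953
n23	n30	0.966
n23	n31	0.861
n23	n32	0.923
n23	n34	0.969
n23	n36	0.928
n23	n37	0.944
n23	n38	0.928
n23	n39	0.896
n24	n28	0.827
n24	n30	0.878
n24	n31	0.889
n24	n33	0.865
n24	n34	0.828
n24	n35	0.859
n24	n37	0.857
n24	n38	0.872
n25	n27	0.842
n25	n29	0.898
n25	n31	0.939
n25	n33	0.877
n25	n34	0.929
n25	n35	0.895
n25	n36	0.88
n25	n38	0.853
n25	n39	0.939
n26	n27	0.823
n26	n28	0.902
n26	n29	0.901
n26	n30	0.967
n26	n32	0.84
n26	n33	0.952
n26	n34	0.9
n26	n38	0.939
n26	n39	0.893
n27	n28	0.843
n27	n29	0.974
n27	n30	0.973
n27	n31	0.944
n27	n35	0.825
n27	n36	0.927
n27	n37	0.875
n27	n38	0.865
n27	n40	0.865
n28	n30	0.842
n28	n31	0.97
n28	n32	0.951
n28	n33	0.857
n28	n34	0.86
n28	n36	0.836
n28	n37	0.913
n28	n38	0.861
n28	n40	0.838
n29	n30	0.926
n29	n33	0.907
n29	n36	0.928
n29	n37	0.864
n29	n38	0.85
n29	n39	0.821
n29	n40	0.932
n29	n54	0.835
n30	n32	0.939
n30	n34	0.958
n30	n36	0.967
n30	n37	0.979
n30	n38	0.93
n30	n40	0.96
n31	n32	0.957
n31	n33	0.944
n31	n35	0.85
n31	n38	0.826
n31	n39	0.966
n31	n40	0.896
n31	n41	0.802
n31	n52	0.834
n32	n34	0.85
n32	n35	0.934
n32	n37	0.909
n32	n38	0.903
n32	n39	0.846
n32	n40	0.887
n32	n48	0.826
n33	n34	0.931
n33	n38	0.949
n33	n39	0.977
n33	n42	0.829
n34	n35	0.976
n34	n36	0.965
n34	n38	0.971
n34	n40	0.919
n35	n36	0.972
n35	n38	0.877
n35	n40	0.949
n35	n51	0.822
n36	n38	0.86
n36	n40	0.898
n37	n38	0.88
n37	n40	0.951
n38	n40	0.963
n38	n59	0.811
n39	n40	0.887
n41	n42	0.932
n41	n43	0.969
n41	n44	0.877
n41	n45	0.929
n41	n46	0.86
n41	n47	0.852
n41	n48	0.909
n41	n51	0.842
n41	n52	0.844
n41	n54	0.893
n41	n58	0.937
n41	n59	0.833
n41	n60	0.874
n42	n43	0.957
n42	n45	0.92
n42	n46	0.834
n42	n47	0.978
n42	n49	0.895
n42	n51	0.97
n42	n52	0.841
n42	n55	0.861
n42	n56	0.862
n42	n57	0.846
n42	n58	0.829
n43	n44	0.943
n43	n45	0.971
n43	n46	0.831
n43	n48	0.942
n43	n49	0.914
n43	n50	0.839
n43	n52	0.862
n43	n56	0.912
n43	n57	0.859
n43	n58	0.878
n43	n59	0.913
n43	n60	0.926
n44	n47	0.97
n44	n48	0.85
n44	n50	0.859
n44	n51	0.969
n44	n52	0.851
n44	n54	0.888
n44	n56	0.861
n44	n57	0.903
n44	n59	0.897
n44	n60	0.863
n45	n47	0.853
n45	n48	0.979
n45	n49	0.837
n45	n50	0.909
n45	n51	0.822
n45	n52	0.968
n45	n53	0.877
n45	n56	0.863
n45	n57	0.958
n45	n59	0.948
n46	n47	0.932
n46	n49	0.906
n46	n51	0.938
n46	n53	0.822
n46	n54	0.832
n46	n55	0.879
n46	n56	0.979
n46	n57	0.841
n46	n58	0.925
n46	n59	0.928
n46	n60	0.923
n47	n48	0.854
n47	n49	0.889
n47	n50	0.979
n47	n51	0.875
n47	n52	0.955
n47	n53	0.831
n47	n54	0.972
n47	n58	0.861
n48	n49	0.946
n48	n51	0.904
n48	n52	0.824
n48	n54	0.916
n48	n55	0.953
n48	n56	0.952
n48	n57	0.948
n48	n58	0.916
n49	n51	0.921
n49	n52	0.929
n49	n53	0.948
n49	n59	0.907
n49	n60	0.823
n50	n51	0.834
n50	n53	0.963
n50	n55	0.902
n50	n56	0.832
n50	n57	0.866
n50	n58	0.905
n51	n52	0.964
n51	n53	0.888
n51	n54	0.88
n51	n55	0.88
n51	n60	0.956
n52	n54	0.95
n52	n55	0.867
n52	n56	0.96
n52	n59	0.903
n53	n54	0.972
n53	n55	0.837
n53	n59	0.926
n54	n55	0.834
n54	n58	0.832
n54	n60	0.908
n55	n57	0.93
n55	n59	0.945
n55	n60	0.906
n56	n57	0.924
n56	n58	0.917
n56	n60	0.825
n57	n59	0.852
n57	n60	0.974
n58	n59	0.928
n58	n60	0.827
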