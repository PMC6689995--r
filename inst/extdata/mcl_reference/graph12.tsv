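gene_a	gene_b	r
n01	n02	0.879
n01	n03	0.939
n01	n04	0.892
n01	n06	0.961
n01	n07	0.923
n01	n10	0.945
n01	n12	0.834
n01	n15	0.922
n01	n17	0.917
n01	n18	0.909
n01	n19	0.842
n01	n20	0.898
n01	n28	0.822
n01	n46	0.84
n02	n03	0.937
n02	n06	0.855
n02	n08	0.933
n02	n09	0.873
n02	n10	0.921
n02	n11	0.931
n02	n12	0.964
n02	n13	0.98
n02	n14	0.892
n02	n15	0.899
n02	n16	0.959
n02	n17	0.93
n02	n18	0.844
n02	n19	0.832
n02	n36	0.808
n03	n04	0.87
n03	n06	0.933
n03	n07	0.958
n03	n09	0.871
n03	n10	0.979
n03	n11	0.876
n03	n12	0.84
n03	n13	0.912
n03	n17	0.828
n03	n18	0.892
n03	n19	0.86
n03	n41	0.805
n04	n07	0.853
n04	n09	0.932
n04	n11	0.906
n04	n12	0.943
n04	n13	0.934
n04	n15	0.907
n04	n16	0.939
n04	n17	0.855
n04	n19	0.941
n04	n48	0.837
n05	n06	0.831
n05	n07	0.962
n05	n08	0.972
n05	n09	0.946
n05	n10	0.894
n05	n11	0.973
n05	n12	0.923
n05	n13	0.941
n05	n14	0.92
n05	n15	0.965
n05	n17	0.956
n05	n19	0.84
n05	n20	0.85
n05	n21	0.803
n06	n07	0.913
n06	n08	0.883
n06	n09	0.947
n06	n10	0.936
n06	n13	0.868
n06	n14	0.845
n06	n18	0.934
n06	n19	0.925
n06	n44	0.801
n07	n08	0.959
n07	n09	0.934
n07	n12	0.942
n07	n13	0.969
n07	n17	0.825
n07	n18	0.834
n08	n10	0.945
n08	n11	0.932
n08	n13	0.835
n08	n15	0.919
n08	n16	0.934
n08	n17	0.821
n08	n18	0.934
n08	n19	0.974
n08	n48	0.807
n09	n10	0.89
n09	n11	0.872
n09	n12	0.833
n09	n14	0.865
n09	n16	0.93
n09	n19	0.917
n09	n20	0.833
n10	n12	0.93
n10	n15	0.907
n10	n17	0.974
n10	n50	0.817
n11	n14	0.846
n11	n15	0.937
n11	n16	0.86
n11	n18	0.967
n11	n19	0.904
n11	n20	0.876
n12	n15	0.828
n12	n19	0.885
n13	n15	0.833
n13	n19	0.856
n13	n20	0.894
n14	n15	0.84
n14	n17	0.824
n14	n18	0.946
n14	n20	0.917
n15	n16	0.956
n15	n17	0.896
n15	n18	0.974
n15	n19	0.962
n15	n20	0.938
n16	n17	0.887
n16	n18	0.94
n16	n19	0.945
n16	n20	0.898
n17	n20	0.912
n18	n19	0.963
n18	n32	0.835
n19	n20	0.98
n19	n26	0.815
n20	n38	0.818
n21	n22	0.895
n21	n26	0.897
n21	n31	0.921
n21	n32	0.87
n21	n33	0.83
n21	n35	0.966
n21	n37	0.962
n21	n39	0.935
n22	n24	0.9
n22	n27	0.925
n22	n30	0.883
n22	n32	0.948
n22	n33	0.975
n22	n34	0.889
n22	n35	0.835
n22	n36	0.848
n22	n37	0.953
n22	n39	0.941
n23	n24	0.853
n23	n26	0.971
n23	n29	0.834
n23	n30	0.852
n23	n31	0.89
n23	n33	0.899
n23	n34	0.825
n23	n35	0.851
n23	n36	0.837
n23	n40	0.9
n24	n25	0.854
n24	n26	0.909
n24	n27	0.909
n24	n32	0.883
n24	n35	0.898
n24	n36	0.938
n24	n39	0.898
n25	n26	0.979
n25	n27	0.888
n25	n28	0.925
n25	n30	0.964
n25	n32	0.903
n25	n33	0.87
n25	n34	0.879
n25	n35	0.942
n25	n36	0.92
n25	n37	0.975
n25	n39	0.94
n25	n48	0.829
n26	n27	0.847
n26	n29	0.906
n26	n30	0.858
n26	n33	0.846
n26	n34	0.827
n26	n35	0.942
n26	n36	0.824
n26	n37	0.907
n26	n39	0.969
n26	n40	0.935
n26	n52	0.832
n27	n30	0.969
n27	n31	0.823
n27	n32	0.916
n27	n35	0.932
n27	n36	0.976
n27	n37	0.94
n27	n38	0.954
n27	n39	0.844
n27	n40	0.934
n28	n29	0.942
n28	n30	0.88
n28	n31	0.885
n28	n32	0.945
n28	n35	0.917
n28	n38	0.874
n28	n39	0.971
n28	n40	0.841
n28	n44	0.802
n29	n30	0.952
n29	n31	0.898
n29	n33	0.84
n29	n35	0.902
n29	n36	0.957
n29	n37	0.952
n30	n31	0.862
n30	n32	0.832
n30	n34	0.942
n30	n35	0.878
n30	n36	0.868
n30	n37	0.917
n30	n40	0.872
n31	n32	0.914
n31	n33	0.85
n31	n34	0.933
n31	n36	0.839
n31	n37	0.833
n31	n38	0.878
n31	n40	0.823
n32	n36	0.861
n32	n37	0.891
n32	n38	0.98
n32	n39	0.901
n32	n40	0.92
n32	n46	0.832
n32	n50	0.837
n32	n55	0.83
n33	n38	0.878
n33	n40	0.892
n34	n35	0.952
n34	n37	0.955
n34	n38	0.826
n35	n38	0.879
n36	n37	0.908
n36	n38	0.938
n36	n39	0.97
n36	n40	0.968
n37	n38	0.838
n37	n39	0.885
n37	n40	0.853
n38	n39	0.858
n39	n40	0.888
n40	n42	0.837
n40	n50	0.801
n40	n53	0.815
n41	n42	0.952
n41	n43	0.978
n41	n44	0.954
n41	n45	0.898
n41	n46	0.844
n41	n48	0.865
n41	n49	0.89
n41	n50	0.822
n41	n51	0.908
n41	n53	0.896
n41	n54	0.865
n41	n56	0.931
n41	n58	0.972
n41	n59	0.937
n41	n60	0.923
n42	n43	0.849
n42	n46	0.947
n42	n48	0.914
n42	n49	0.853
n42	n52	0.883
n42	n53	0.978
n42	n54	0.922
n42	n56	0.825
n42	n57	0.951
n42	n58	0.85
n42	n60	0.828
n43	n45	0.833
n43	n48	0.969
n43	n49	0.842
n43	n50	0.921
n43	n51	0.863
n43	n53	0.978
n43	n56	0.93
n43	n57	0.972
n43	n58	0.841
n43	n60	0.862
n44	n46	0.971
n44	n47	0.831
n44	n48	0.888
n44	n51	0.824
n44	n52	0.943
n44	n53	0.855
n44	n57	0.969
n44	n58	0.832
n44	n59	0.88
n44	n60	0.931
n45	n47	0.867
n45	n49	0.85
n45	n50	0.916
n45	n52	0.853
n45	n53	0.902
n45	n54	0.972
n45	n56	0.971
n45	n59	0.978
n45	n60	0.95
n46	n52	0.936
n46	n54	0.876
n46	n55	0.978
n46	n56	0.825
n46	n58	0.921
n46	n59	0.821
n47	n48	0.955
n47	n49	0.912
n47	n50	0.856
n47	n52	0.846
n47	n54	0.897
n47	n55	0.914
n47	n58	0.881
n47	n59	0.821
n48	n51	0.876
n48	n52	0.977
n48	n53	0.822
n48	n56	0.907
n48	n57	0.978
n48	n58	0.845
n48	n59	0.956
n48	n60	0.933
n49	n50	0.823
n49	n52	0.823
n49	n54	0.876
n49	n58	0.824
n49	n59	0.828
n50	n51	0.859
n50	n52	0.97
n50	n53	0.824
n50	n54	0.829
n50	n56	0.84
n50	n58	0.939
n51	n52	0.899
n51	n53	0.953
n51	n54	0.857
n51	n55	0.908
n51	n56	0.943
n51	n57	0.856
n51	n59	0.823
n51	n60	0.879
n52	n53	0.9
n52	n54	0.838
n52	n57	0.94
n52	n58	0.959
n52	n59	0.821
n53	n54	0.84
n53	n56	0.826
n53	n57	0.845
n53	n58	0.977
n53	n59	0.899
n53	n60	0.889
n54	n55	0.845
n54	n56	0.862
n54	n57	0.961
n55	n56	0.858
n55	n57	0.933
n55	n58	0.855
n55	n59	0.953
n55	n60	0.953
n56	n59	0.827
n57	n58	0.822
n59	n60	0.876
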