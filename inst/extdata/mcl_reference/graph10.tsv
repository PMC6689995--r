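gene_a	gene_b	r
n01	n02	0.851
n01	n03	0.928
n01	n08	0.948
n01	n12	0.821
n01	n13	0.864
n01	n15	0.829
n01	n16	0.952
n01	n17	0.861
n01	n18	0.869
n01	n19	0.821
n01	n41	0.831
n02	n05	0.83
n02	n06	0.842
n02	n07	0.901
n02	n08	0.871
n02	n09	0.942
n02	n12	0.879
n02	n14	0.859
n02	n15	0.91
n02	n16	0.92
n02	n18	0.979
n02	n20	0.965
n03	n04	0.933
n03	n05	0.88
n03	n06	0.856
n03	n07	0.956
n03	n09	0.936
n03	n10	0.935
n03	n11	0.98
n03	n12	0.908
n03	n13	0.95
n03	n18	0.89
n03	n33	0.807
n04	n06	0.863
n04	n08	0.951
n04	n09	0.972
n04	n10	0.83
n04	n12	0.968
n04	n15	0.88
n04	n16	0.903
n04	n17	0.973
n04	n19	0.945
n05	n06	0.973
n05	n07	0.845
n05	n11	0.952
n05	n12	0.914
n05	n13	0.843
n05	n14	0.854
n05	n15	0.908
n05	n16	0.832
n05	n17	0.895
n05	n18	0.926
n05	n19	0.915
n05	n20	0.969
n05	n31	0.803
n06	n07	0.909
n06	n08	0.851
n06	n09	0.856
n06	n12	0.95
n06	n14	0.852
n06	n15	0.885
n06	n19	0.93
n07	n08	0.864
n07	n09	0.935
n07	n10	0.941
n07	n12	0.822
n07	n16	0.949
n07	n17	0.867
n07	n20	0.889
n07	n31	0.831
n07	n32	0.824
n07	n35	0.839
n07	n51	0.835
n08	n10	0.947
n08	n11	0.973
n08	n12	0.866
n08	n16	0.955
n08	n17	0.916
n08	n18	0.83
n08	n19	0.868
n08	n20	0.867
n08	n39	0.826
n08	n53	0.837
n09	n11	0.86
n09	n12	0.929
n09	n13	0.956
n09	n14	0.885
n09	n17	0.923
n09	n18	0.869
n09	n19	0.892
n09	n52	0.811
n10	n13	0.879
n10	n16	0.951
n10	n17	0.824
n10	n18	0.876
n10	n19	0.926
n10	n20	0.977
n10	n38	0.818
n11	n12	0.856
n11	n13	0.864
n11	n15	0.945
n11	n18	0.93
n11	n19	0.85
n11	n20	0.923
n12	n13	0.844
n12	n15	0.89
n12	n17	0.922
n12	n18	0.922
n12	n19	0.897
n12	n20	0.887
n13	n14	0.938
n13	n17	0.831
n13	n18	0.952
n13	n19	0.847
n13	n20	0.978
n14	n15	0.841
n14	n16	0.898
n14	n18	0.833
n14	n20	0.921
n14	n44	0.805
n15	n16	0.87
n15	n17	0.897
n16	n38	0.819
n16	n42	0.838
n17	n18	0.851
n17	n19	0.867
n18	n20	0.942
n18	n51	0.824
n19	n20	0.916
n19	n34	0.816
n20	n36	0.823
n20	n53	0.831
n21	n22	0.877
n21	n24	0.879
n21	n27	0.826
n21	n28	0.834
n21	n30	0.852
n21	n31	0.92
n21	n32	0.93
n21	n33	0.903
n21	n34	0.89
n21	n37	0.832
n21	n40	0.954
n22	n28	0.885
n22	n34	0.907
n22	n36	0.964
n22	n37	0.896
n22	n40	0.835
n22	n50	0.82
n23	n24	0.879
n23	n25	0.923
n23	n26	0.871
n23	n27	0.932
n23	n28	0.84
n23	n33	0.896
n23	n34	0.888
n23	n36	0.95
n23	n39	0.972
n23	n43	0.83
n23	n47	0.834
n24	n26	0.969
n24	n28	0.837
n24	n29	0.828
n24	n30	0.887
n24	n31	0.955
n24	n33	0.897
n24	n34	0.831
n24	n37	0.913
n24	n38	0.836
n24	n57	0.828
n25	n27	0.883
n25	n28	0.911
n25	n30	0.841
n25	n31	0.831
n25	n32	0.878
n25	n33	0.939
n25	n34	0.916
n25	n36	0.957
n25	n38	0.864
n25	n39	0.821
n25	n40	0.833
n26	n31	0.875
n26	n33	0.939
n26	n34	0.945
n26	n35	0.973
n26	n36	0.83
n26	n37	0.929
n27	n31	0.876
n27	n32	0.876
n27	n33	0.959
n27	n35	0.874
n27	n36	0.844
n27	n37	0.903
n27	n38	0.98
n27	n39	0.889
n27	n55	0.819
n27	n57	0.837
n28	n29	0.94
n28	n30	0.889
n28	n31	0.835
n28	n32	0.839
n28	n33	0.822
n28	n34	0.942
n28	n37	0.928
n28	n38	0.928
n28	n40	0.907
n29	n31	0.905
n29	n32	0.861
n29	n37	0.836
n29	n39	0.833
n29	n40	0.891
n30	n32	0.824
n30	n33	0.881
n30	n36	0.871
n30	n37	0.92
n30	n38	0.841
n30	n39	0.929
n30	n40	0.904
n31	n35	0.848
n31	n40	0.915
n31	n46	0.812
n32	n33	0.895
n32	n34	0.899
n32	n35	0.979
n32	n36	0.91
n33	n34	0.916
n33	n36	0.93
n33	n38	0.829
n33	n39	0.901
n34	n36	0.888
n34	n37	0.887
n34	n38	0.892
n34	n39	0.879
n34	n40	0.904
n34	n45	0.84
n35	n36	0.901
n35	n38	0.825
n35	n40	0.963
n36	n37	0.932
n36	n38	0.969
n37	n38	0.955
n37	n49	0.821
n38	n39	0.872
n41	n44	0.936
n41	n47	0.883
n41	n55	0.86
n41	n56	0.878
n41	n58	0.842
n41	n60	0.923
n42	n45	0.978
n42	n49	0.867
n42	n50	0.95
n42	n52	0.903
n42	n55	0.973
n42	n56	0.897
n42	n57	0.969
n42	n60	0.945
n43	n44	0.932
n43	n46	0.828
n43	n47	0.904
n43	n48	0.823
n43	n49	0.935
n43	n50	0.831
n43	n52	0.855
n43	n56	0.935
n43	n60	0.821
n44	n45	0.923
n44	n46	0.947
n44	n47	0.932
n44	n48	0.918
n44	n51	0.959
n44	n54	0.91
n44	n56	0.943
n44	n58	0.935
n44	n59	0.967
n45	n46	0.882
n45	n47	0.962
n45	n51	0.888
n45	n53	0.869
n45	n55	0.879
n45	n56	0.949
n45	n59	0.96
n45	n60	0.869
n46	n48	0.856
n46	n50	0.908
n46	n51	0.888
n46	n52	0.974
n46	n53	0.944
n46	n54	0.969
n46	n57	0.961
n46	n58	0.896
n46	n59	0.868
n46	n60	0.94
n47	n49	0.961
n47	n51	0.838
n47	n52	0.974
n47	n53	0.914
n47	n54	0.925
n47	n55	0.931
n47	n59	0.91
n47	n60	0.92
n48	n49	0.835
n48	n51	0.977
n48	n52	0.898
n48	n53	0.88
n48	n55	0.868
n48	n56	0.921
n48	n57	0.845
n48	n60	0.96
n49	n51	0.923
n49	n53	0.869
n49	n54	0.96
n49	n55	0.905
n50	n51	0.836
n50	n52	0.869
n50	n53	0.849
n50	n55	0.967
n50	n56	0.931
n50	n57	0.968
n50	n58	0.837
n50	n60	0.862
n51	n53	0.845
n51	n54	0.922
n51	n56	0.909
n51	n57	0.971
n51	n59	0.906
n51	n60	0.893
n52	n53	0.893
n52	n54	0.82
n52	n56	0.924
n52	n58	0.901
n52	n59	0.822
n53	n54	0.84
n53	n55	0.955
n53	n59	0.894
n54	n55	0.965
n54	n56	0.847
n54	n57	0.953
n54	n59	0.878
n55	n58	0.848
n55	n59	0.835
n55	n60	0.916
n56	n57	0.899
n56	n59	0.862
n56	n60	0.907
n57	n60	0.925
n58	n59	0.842
n59	n60	0.873
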