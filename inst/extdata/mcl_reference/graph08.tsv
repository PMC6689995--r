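gene_a	gene_b	r
n01	n06	0.856
n01	n09	0.955
n01	n11	0.971
n01	n12	0.87
n01	n13	0.907
n01	n14	0.921
n01	n15	0.964
n01	n17	0.873
n01	n19	0.903
n01	n20	0.94
n02	n03	0.953
n02	n05	0.939
n02	n06	0.969
n02	n07	0.836
n02	n09	0.849
n02	n10	0.828
n02	n13	0.869
n02	n14	0.871
n02	n15	0.847
n02	n18	0.846
n02	n19	0.96
n02	n29	0.836
n02	n36	0.812
n03	n05	0.894
n03	n09	0.837
n03	n12	0.86
n03	n13	0.826
n03	n17	0.87
n03	n18	0.9
n03	n19	0.936
n03	n20	0.926
n03	n49	0.838
n04	n06	0.959
n04	n08	0.822
n04	n09	0.828
n04	n11	0.874
n04	n13	0.944
n04	n14	0.885
n04	n17	0.894
n04	n19	0.866
n04	n20	0.891
n04	n53	0.8
n05	n06	0.954
n05	n07	0.918
n05	n08	0.875
n05	n13	0.942
n05	n15	0.842
n05	n17	0.961
n05	n19	0.924
n05	n20	0.84
n06	n07	0.918
n06	n12	0.945
n06	n13	0.948
n06	n15	0.87
n06	n16	0.821
n06	n20	0.891
n06	n40	0.809
n07	n08	0.917
n07	n09	0.971
n07	n10	0.92
n07	n11	0.822
n07	n13	0.887
n07	n14	0.946
n07	n15	0.937
n07	n17	0.951
n07	n18	0.861
n07	n20	0.833
n08	n09	0.95
n08	n10	0.97
n08	n11	0.822
n08	n12	0.918
n08	n14	0.885
n08	n19	0.869
n09	n11	0.93
n09	n12	0.951
n09	n13	0.866
n09	n14	0.936
n09	n15	0.932
n09	n16	0.918
n09	n17	0.938
n10	n13	0.971
n10	n14	0.944
n10	n16	0.957
n10	n17	0.862
n10	n18	0.876
n10	n20	0.837
n10	n27	0.818
n10	n50	0.829
n11	n13	0.882
n11	n14	0.929
n11	n17	0.889
n11	n18	0.929
n11	n20	0.956
n11	n23	0.823
n11	n50	0.833
n12	n15	0.841
n12	n16	0.833
n12	n17	0.979
n12	n20	0.897
n12	n43	0.813
n13	n15	0.956
n14	n15	0.841
n14	n17	0.975
n15	n18	0.944
n15	n20	0.974
n15	n34	0.815
n15	n48	0.805
n16	n19	0.955
n16	n52	0.817
n16	n55	0.818
n17	n18	0.918
n17	n19	0.928
n17	n20	0.979
n17	n29	0.83
n19	n39	0.819
n20	n37	0.812
n20	n50	0.834
n21	n24	0.918
n21	n26	0.918
n21	n27	0.833
n21	n28	0.917
n21	n29	0.857
n21	n33	0.951
n21	n34	0.867
n21	n35	0.838
n21	n36	0.877
n21	n37	0.941
n21	n38	0.824
n21	n39	0.963
n21	n40	0.904
n22	n24	0.918
n22	n25	0.945
n22	n29	0.936
n22	n31	0.937
n22	n33	0.875
n22	n35	0.907
n22	n38	0.943
n23	n24	0.945
n23	n25	0.92
n23	n27	0.822
n23	n29	0.855
n23	n30	0.958
n23	n31	0.857
n23	n32	0.932
n23	n33	0.856
n23	n34	0.861
n23	n35	0.894
n23	n36	0.887
n24	n26	0.967
n24	n27	0.966
n24	n28	0.919
n24	n30	0.86
n24	n31	0.955
n24	n32	0.907
n24	n34	0.904
n24	n35	0.826
n24	n36	0.889
n24	n38	0.923
n24	n39	0.906
n25	n27	0.876
n25	n28	0.952
n25	n29	0.946
n25	n30	0.948
n25	n31	0.92
n25	n32	0.829
n25	n35	0.825
n25	n38	0.867
n25	n39	0.886
n26	n27	0.868
n26	n28	0.906
n26	n29	0.896
n26	n30	0.861
n26	n31	0.894
n26	n33	0.972
n26	n34	0.85
n26	n35	0.876
n26	n36	0.92
n26	n39	0.93
n26	n40	0.955
n27	n28	0.899
n27	n29	0.849
n27	n30	0.872
n27	n31	0.897
n27	n32	0.869
n27	n34	0.856
n27	n35	0.841
n27	n36	0.864
n27	n37	0.909
n27	n39	0.927
n28	n29	0.908
n28	n31	0.915
n28	n33	0.88
n28	n36	0.903
n28	n40	0.86
n29	n30	0.839
n29	n31	0.881
n29	n37	0.955
n29	n38	0.839
n29	n43	0.83
n30	n31	0.883
n30	n34	0.886
n30	n36	0.974
n30	n38	0.94
n30	n39	0.862
n30	n40	0.87
n31	n32	0.823
n31	n34	0.95
n31	n35	0.828
n31	n38	0.849
n31	n39	0.973
n31	n40	0.946
n32	n33	0.965
n32	n34	0.908
n32	n35	0.911
n32	n36	0.919
n32	n39	0.945
n32	n40	0.896
n32	n42	0.803
n33	n34	0.927
n33	n35	0.918
n33	n36	0.938
n33	n37	0.892
n33	n38	0.959
n34	n35	0.902
n34	n37	0.861
n34	n38	0.898
n34	n39	0.904
n34	n47	0.837
n35	n36	0.821
n35	n39	0.898
n35	n40	0.931
n36	n37	0.923
n36	n38	0.928
n36	n40	0.831
n37	n38	0.913
n37	n39	0.957
n37	n40	0.887
n38	n39	0.833
n38	n40	0.915
n39	n40	0.911
n39	n53	0.8
n41	n42	0.894
n41	n45	0.913
n41	n46	0.964
n41	n51	0.944
n41	n55	0.951
n41	n58	0.963
n41	n59	0.865
n41	n60	0.881
n42	n44	0.864
n42	n45	0.822
n42	n47	0.899
n42	n48	0.842
n42	n49	0.919
n42	n51	0.928
n42	n52	0.896
n42	n53	0.825
n42	n55	0.828
n42	n56	0.874
n42	n57	0.824
n42	n59	0.839
n42	n60	0.918
n43	n46	0.891
n43	n47	0.901
n43	n48	0.824
n43	n49	0.874
n43	n51	0.927
n43	n52	0.972
n43	n53	0.911
n43	n54	0.903
n43	n57	0.861
n43	n59	0.864
n44	n45	0.945
n44	n46	0.912
n44	n47	0.932
n44	n48	0.876
n44	n49	0.853
n44	n50	0.979
n44	n51	0.932
n44	n54	0.836
n44	n55	0.94
n44	n57	0.847
n44	n60	0.958
n45	n46	0.939
n45	n47	0.947
n45	n51	0.943
n45	n52	0.922
n45	n53	0.953
n45	n57	0.871
n45	n58	0.859
n45	n60	0.918
n46	n47	0.942
n46	n48	0.916
n46	n49	0.836
n46	n50	0.908
n46	n51	0.885
n46	n52	0.847
n46	n54	0.875
n46	n55	0.865
n46	n56	0.861
n46	n57	0.849
n47	n48	0.953
n47	n50	0.945
n47	n51	0.911
n47	n54	0.908
n47	n57	0.847
n47	n58	0.886
n47	n59	0.899
n48	n49	0.924
n48	n51	0.842
n48	n52	0.877
n48	n53	0.855
n48	n54	0.835
n48	n58	0.924
n48	n59	0.943
n49	n50	0.929
n49	n54	0.84
n49	n55	0.975
n49	n56	0.882
n49	n57	0.905
n49	n58	0.825
n50	n51	0.944
n50	n52	0.961
n50	n53	0.918
n50	n54	0.961
n50	n55	0.826
n50	n56	0.841
n50	n57	0.89
n50	n58	0.906
n50	n60	0.952
n51	n52	0.894
n51	n53	0.954
n51	n55	0.961
n51	n56	0.894
n52	n53	0.886
n52	n55	0.953
n52	n56	0.899
n52	n57	0.922
n52	n58	0.868
n52	n59	0.879
n52	n60	0.879
n53	n56	0.932
n53	n58	0.978
n53	n59	0.843
n53	n60	0.918
n54	n55	0.89
n54	n56	0.951
n54	n57	0.861
n54	n58	0.889
n54	n59	0.956
n55	n56	0.914
n55	n57	0.875
n55	n58	0.937
n57	n58	0.863
n57	n59	0.923
n58	n60	0.876
n59	n60	0.976
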