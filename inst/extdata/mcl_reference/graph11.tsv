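gene_a	gene_b	r
n01	n03	0.864
n01	n05	0.956
n01	n07	0.963
n01	n08	0.917
n01	n10	0.942
n01	n11	0.878
n01	n12	0.915
n01	n13	0.876
n01	n14	0.854
n01	n15	0.857
n01	n16	0.901
n01	n17	0.85
n01	n18	0.842
n01	n20	0.853
n01	n46	0.806
n02	n04	0.901
n02	n07	0.872
n02	n12	0.912
n02	n13	0.974
n02	n15	0.845
n02	n19	0.913
n02	n29	0.835
n03	n06	0.889
n03	n14	0.913
n03	n15	0.825
n03	n17	0.895
n03	n18	0.868
n03	n19	0.85
n04	n05	0.853
n04	n07	0.947
n04	n10	0.934
n04	n11	0.964
n04	n12	0.888
n04	n14	0.854
n04	n16	0.88
n04	n18	0.933
n04	n19	0.822
n04	n22	0.804
n04	n34	0.828
n05	n06	0.826
n05	n07	0.907
n05	n12	0.86
n05	n13	0.959
n05	n14	0.919
n05	n17	0.857
n05	n19	0.828
n05	n20	0.916
n05	n56	0.819
n06	n08	0.886
n06	n09	0.95
n06	n13	0.967
n06	n14	0.968
n06	n17	0.845
n06	n18	0.958
n06	n20	0.893
n06	n49	0.825
n06	n54	0.809
n07	n09	0.948
n07	n10	0.866
n07	n11	0.867
n07	n19	0.976
n08	n12	0.834
n08	n13	0.929
n08	n15	0.849
n08	n17	0.871
n08	n20	0.853
n08	n45	0.804
n08	n58	0.838
n09	n10	0.953
n09	n11	0.972
n09	n12	0.922
n09	n14	0.95
n09	n20	0.87
n10	n11	0.884
n10	n13	0.924
n10	n15	0.874
n10	n16	0.873
n10	n17	0.859
n10	n18	0.865
n10	n19	0.896
n11	n12	0.921
n11	n13	0.97
n11	n14	0.932
n11	n17	0.962
n11	n18	0.916
n11	n19	0.826
n11	n20	0.979
n12	n13	0.93
n12	n14	0.919
n12	n15	0.942
n12	n17	0.893
n12	n18	0.956
n12	n19	0.877
n12	n20	0.839
n12	n21	0.812
n13	n14	0.875
n13	n16	0.889
n13	n17	0.908
n13	n20	0.933
n13	n25	0.834
n14	n17	0.975
n14	n18	0.88
n15	n16	0.929
n15	n17	0.946
n15	n18	0.945
n15	n19	0.971
n15	n20	0.909
n15	n24	0.828
n15	n53	0.816
n16	n17	0.927
n16	n18	0.932
n16	n19	0.978
n16	n20	0.93
n16	n42	0.815
n17	n44	0.801
n19	n20	0.903
n20	n25	0.809
n20	n32	0.802
n21	n24	0.932
n21	n26	0.943
n21	n28	0.907
n21	n29	0.952
n21	n31	0.925
n21	n32	0.899
n21	n33	0.907
n21	n34	0.964
n21	n36	0.945
n21	n37	0.83
n21	n38	0.856
n21	n39	0.841
n22	n23	0.915
n22	n26	0.825
n22	n28	0.876
n22	n29	0.907
n22	n33	0.933
n22	n35	0.882
n22	n36	0.944
n22	n39	0.939
n22	n40	0.93
n23	n24	0.891
n23	n25	0.891
n23	n26	0.961
n23	n28	0.936
n23	n29	0.891
n23	n30	0.841
n23	n31	0.861
n23	n32	0.903
n23	n33	0.969
n23	n37	0.898
n23	n38	0.95
n23	n39	0.894
n24	n27	0.98
n24	n29	0.952
n24	n33	0.926
n24	n34	0.832
n24	n35	0.82
n24	n36	0.92
n24	n37	0.905
n24	n38	0.912
n24	n39	0.894
n24	n40	0.921
n25	n26	0.897
n25	n27	0.975
n25	n29	0.884
n25	n31	0.821
n25	n35	0.84
n25	n36	0.972
n25	n39	0.87
n26	n27	0.851
n26	n29	0.976
n26	n31	0.951
n26	n32	0.966
n26	n34	0.919
n26	n35	0.886
n26	n38	0.891
n26	n39	0.927
n27	n28	0.943
n27	n29	0.828
n27	n32	0.904
n27	n33	0.821
n27	n34	0.83
n28	n30	0.909
n28	n31	0.857
n28	n33	0.91
n28	n34	0.874
n28	n35	0.929
n28	n38	0.878
n28	n39	0.959
n28	n48	0.811
n29	n31	0.836
n29	n32	0.951
n29	n35	0.879
n29	n36	0.858
n29	n39	0.833
n30	n33	0.912
n30	n34	0.911
n30	n37	0.864
n30	n38	0.878
n30	n39	0.847
n30	n54	0.83
n31	n32	0.877
n31	n33	0.947
n31	n36	0.905
n32	n34	0.902
n32	n35	0.91
n32	n36	0.843
n32	n37	0.863
n32	n38	0.959
n32	n39	0.942
n32	n40	0.97
n32	n58	0.824
n33	n35	0.92
n33	n37	0.821
n33	n39	0.848
n33	n40	0.967
n33	n60	0.82
n34	n35	0.97
n34	n37	0.869
n34	n38	0.892
n34	n39	0.888
n35	n37	0.939
n35	n40	0.87
n35	n43	0.828
n36	n38	0.936
n36	n39	0.961
n37	n38	0.851
n38	n39	0.925
n38	n47	0.834
n39	n40	0.869
n40	n54	0.805
n41	n44	0.96
n41	n46	0.836
n41	n47	0.926
n41	n48	0.838
n41	n49	0.908
n41	n51	0.954
n41	n52	0.842
n41	n57	0.971
n42	n43	0.946
n42	n46	0.857
n42	n47	0.822
n42	n48	0.941
n42	n49	0.851
n42	n51	0.92
n42	n52	0.863
n42	n55	0.937
n42	n56	0.922
n42	n57	0.888
n42	n58	0.957
n42	n59	0.958
n43	n44	0.844
n43	n45	0.965
n43	n46	0.854
n43	n47	0.842
n43	n50	0.82
n43	n53	0.967
n43	n56	0.938
n43	n57	0.836
n43	n58	0.835
n44	n47	0.848
n44	n48	0.878
n44	n49	0.942
n44	n50	0.867
n44	n51	0.832
n44	n52	0.861
n44	n53	0.97
n44	n54	0.939
n44	n55	0.902
n44	n56	0.876
n44	n57	0.913
n44	n59	0.876
n44	n60	0.912
n45	n46	0.837
n45	n47	0.826
n45	n49	0.952
n45	n52	0.832
n45	n54	0.918
n45	n57	0.975
n45	n58	0.844
n45	n59	0.851
n45	n60	0.843
n46	n53	0.956
n46	n55	0.859
n46	n56	0.934
n46	n60	0.848
n47	n48	0.978
n47	n50	0.933
n47	n51	0.862
n47	n52	0.938
n47	n53	0.867
n47	n55	0.899
n47	n56	0.843
n47	n58	0.872
n47	n59	0.944
n47	n60	0.894
n48	n50	0.947
n48	n51	0.97
n48	n53	0.92
n48	n54	0.919
n48	n55	0.94
n48	n56	0.948
n48	n57	0.933
n48	n58	0.974
n48	n60	0.9
n49	n52	0.976
n49	n54	0.852
n49	n56	0.858
n49	n57	0.924
n49	n58	0.839
n49	n60	0.917
n50	n52	0.936
n50	n53	0.948
n50	n55	0.831
n50	n56	0.895
n50	n58	0.951
n50	n60	0.838
n51	n54	0.942
n51	n58	0.849
n51	n59	0.853
n51	n60	0.89
n52	n53	0.942
n52	n55	0.92
n52	n56	0.883
n52	n57	0.938
n53	n55	0.914
n53	n57	0.974
n53	n58	0.906
n53	n59	0.905
n53	n60	0.901
n54	n55	0.836
n54	n56	0.911
n54	n57	0.955
n54	n59	0.975
n54	n60	0.925
n55	n58	0.955
n55	n59	0.978
n55	n60	0.904
n56	n59	0.912
n57	n60	0.879
n58	n60	0.974
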