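index,code,name,class
1,Precentral_L,"Left precentral gyrus",cortical
2,Precentral_R,"Right precentral gyrus",cortical
3,Frontal_Sup_L,"Left superior frontal gyrus, dorsolateral",cortical
4,Frontal_Sup_R,"Right superior frontal gyrus, dorsolateral",cortical
5,Frontal_Sup_Orb_L,"Left superior frontal gyrus, orbital part",cortical
6,Frontal_Sup_Orb_R,"Right superior frontal gyrus, orbital part",cortical
7,Frontal_Mid_L,"Left middle frontal gyrus",cortical
8,Frontal_Mid_R,"Right middle frontal gyrus",cortical
9,Frontal_Mid_Orb_L,"Left middle frontal gyrus, orbital part",cortical
10,Frontal_Mid_Orb_R,"Right middle frontal gyrus, orbital part",cortical
11,Frontal_Inf_Oper_L,"Left inferior frontal gyrus, opercular part",cortical
12,Frontal_Inf_Oper_R,"Right inferior frontal gyrus, opercular part",cortical
13,Frontal_Inf_Tri_L,"Left inferior frontal gyrus, triangular part",cortical
14,Frontal_Inf_Tri_R,"Right inferior frontal gyrus, triangular part",cortical
15,Frontal_Inf_Orb_L,"Left inferior frontal gyrus, orbital part",cortical
16,Frontal_Inf_Orb_R,"Right inferior frontal gyrus, orbital part",cortical
17,Rolandic_Oper_L,"Left rolandic operculum",cortical
18,Rolandic_Oper_R,"Right rolandic operculum",cortical
19,Supp_Motor_Area_L,"Left supplementary motor area",cortical
20,Supp_Motor_Area_R,"Right supplementary motor area",cortical
21,Olfactory_L,"Left olfactory cortex",cortical
22,Olfactory_R,"Right olfactory cortex",cortical
23,Frontal_Sup_Medial_L,"Left superior frontal gyrus, medial",cortical
24,Frontal_Sup_Medial_R,"Right superior frontal gyrus, medial",cortical
25,Frontal_Med_Orb_L,"Left superior frontal gyrus, medial orbital",cortical
26,Frontal_Med_Orb_R,"Right superior frontal gyrus, medial orbital",cortical
27,Rectus_L,"Left gyrus rectus",cortical
28,Rectus_R,"Right gyrus rectus",cortical
29,Insula_L,"Left insula",cortical
30,Insula_R,"Right insula",cortical
31,Cingulum_Ant_L,"Left anterior cingulate gyrus",cortical
32,Cingulum_Ant_R,"Right anterior cingulate gyrus",cortical
33,Cingulum_Mid_L,"Left median cingulate gyrus",cortical
34,Cingulum_Mid_R,"Right median cingulate gyrus",cortical
35,Cingulum_Post_L,"Left posterior cingulate gyrus",cortical
36,Cingulum_Post_R,"Right posterior cingulate gyrus",cortical
37,Hippocampus_L,"Left hippocampus",cortical
38,Hippocampus_R,"Right hippocampus",cortical
39,ParaHippocampal_L,"Left parahippocampal gyrus",cortical
40,ParaHippocampal_R,"Right parahippocampal gyrus",cortical
41,Amygdala_L,"Left amygdala",cortical
42,Amygdala_R,"Right amygdala",cortical
43,Calcarine_L,"Left calcarine fissure and surrounding cortex",cortical
44,Calcarine_R,"Right calcarine fissure and surrounding cortex",cortical
45,Cuneus_L,"Left cuneus",cortical
46,Cuneus_R,"Right cuneus",cortical
47,Lingual_L,"Left lingual gyrus",cortical
48,Lingual_R,"Right lingual gyrus",cortical
49,Occipital_Sup_L,"Left superior occipital gyrus",cortical
50,Occipital_Sup_R,"Right superior occipital gyrus",cortical
51,Occipital_Mid_L,"Left middle occipital gyrus",cortical
52,Occipital_Mid_R,"Right middle occipital gyrus",cortical
53,Occipital_Inf_L,"Left inferior occipital gyrus",cortical
54,Occipital_Inf_R,"Right inferior occipital gyrus",cortical
55,Fusiform_L,"Left fusiform gyrus",cortical
56,Fusiform_R,"Right fusiform gyrus",cortical
57,Postcentral_L,"Left postcentral gyrus",cortical
58,Postcentral_R,"Right postcentral gyrus",cortical
59,Parietal_Sup_L,"Left superior parietal gyrus",cortical
60,Parietal_Sup_R,"Right superior parietal gyrus",cortical
61,Parietal_Inf_L,"Left inferior parietal gyrus",cortical
62,Parietal_Inf_R,"Right inferior parietal gyrus",cortical
63,SupraMarginal_L,"Left supramarginal gyrus",cortical
64,SupraMarginal_R,"Right supramarginal gyrus",cortical
65,Angular_L,"Left angular gyrus",cortical
66,Angular_R,"Right angular gyrus",cortical
67,Precuneus_L,"Left precuneus",cortical
68,Precuneus_R,"Right precuneus",cortical
69,Paracentral_Lobule_L,"Left paracentral lobule",cortical
70,Paracentral_Lobule_R,"Right paracentral lobule",cortical
71,Caudate_L,"Left caudate nucleus",subcortical
72,Caudate_R,"Right caudate nucleus",subcortical
73,Putamen_L,"Left lenticular nucleus, putamen",subcortical
74,Putamen_R,"Right lenticular nucleus, putamen",subcortical
75,Pallidum_L,"Left lenticular nucleus, pallidum",subcortical
76,Pallidum_R,"Right lenticular nucleus, pallidum",subcortical
77,Thalamus_L,"Left thalamus",subcortical
78,Thalamus_R,"Right thalamus",subcortical
79,Heschl_L,"Left Heschl gyrus",cortical
80,Heschl_R,"Right Heschl gyrus",cortical
81,Temporal_Sup_L,"Left superior temporal gyrus",cortical
82,Temporal_Sup_R,"Right superior temporal gyrus",cortical
83,Temporal_Pole_Sup_L,"Left temporal pole: superior temporal gyrus",cortical
84,Temporal_Pole_Sup_R,"Right temporal pole: superior temporal gyrus",cortical
85,Temporal_Mid_L,"Left middle temporal gyrus",cortical
86,Temporal_Mid_R,"Right middle temporal gyrus",cortical
87,Temporal_Pole_Mid_L,"Left temporal pole: middle temporal gyrus",cortical
88,Temporal_Pole_Mid_R,"Right temporal pole: middle temporal gyrus",cortical
89,Temporal_Inf_L,"Left inferior temporal gyrus",cortical
90,Temporal_Inf_R,"Right inferior temporal gyrus",cortical
91,Cerebelum_Crus1_L,"Left cerebellum.Crus1",cerebellar
92,Cerebelum_Crus1_R,"Right cerebellum.Crus1",cerebellar
93,Cerebelum_Crus2_L,"Left cerebellum.Crus2",cerebellar
94,Cerebelum_Crus2_R,"Right cerebellum.Crus2",cerebellar
95,Cerebelum_3_L,"Left cerebellum.3",cerebellar
96,Cerebelum_3_R,"Right cerebellum.3",cerebellar
97,Cerebelum_4_5_L,"Left cerebellum.4.5",cerebellar
98,Cerebelum_4_5_R,"Right cerebellum.4.5",cerebellar
99,Cerebelum_6_L,"Left cerebellum.6",cerebellar
100,Cerebelum_6_R,"Right cerebellum.6",cerebellar
101,Cerebelum_7b_L,"Left cerebellum.7b",cerebellar
102,Cerebelum_7b_R,"Right cerebellum.7b",cerebellar
103,Cerebelum_8_L,"Left cerebellum.8",cerebellar
104,Cerebelum_8_R,"Right cerebellum.8",cerebellar
105,Cerebelum_9_L,"Left cerebellum.9",cerebellar
106,Cerebelum_9_R,"Right cerebellum.9",cerebellar
107,Cerebelum_10_L,"Left cerebellum.10",cerebellar
108,Cerebelum_10_R,"Right cerebellum.10",cerebellar
109,Vermis_1_2,"Vermis.1.2",cerebellar
110,Vermis_3,"Vermis.3",cerebellar
111,Vermis_4_5,"Vermis.4.5",cerebellar
112,Vermis_6,"Vermis.6",cerebellar
113,Vermis_7,"Vermis.7",cerebellar
114,Vermis_8,"Vermis.8",cerebellar
115,Vermis_9,"Vermis.9",cerebellar
116,Vermis_10,"Vermis.10",cerebellar
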