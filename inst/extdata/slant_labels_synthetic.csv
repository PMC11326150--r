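"id","name","tissue_class"
4,"3rd Ventricle","CSF"
11,"4th Ventricle","CSF"
23,"Right Accumbens Area","GM"
30,"Left Accumbens Area","GM"
31,"Right Amygdala","GM"
32,"Left Amygdala","GM"
35,"Brain Stem","WM"
36,"Right Caudate","GM"
37,"Left Caudate","GM"
38,"Right Cerebellum Exterior","GM"
39,"Left Cerebellum Exterior","GM"
40,"Right Cerebellum White Matter","WM"
41,"Left Cerebellum White Matter","WM"
44,"Right Cerebral White Matter","WM"
45,"Left Cerebral White Matter","WM"
46,"CSF","CSF"
47,"Right Hippocampus","GM"
48,"Left Hippocampus","GM"
49,"Right Inferior Lateral Ventricle","CSF"
50,"Left Inferior Lateral Ventricle","CSF"
51,"Right Lateral Ventricle","CSF"
52,"Left Lateral Ventricle","CSF"
55,"Right Pallidum","GM"
56,"Left Pallidum","GM"
57,"Right Putamen","GM"
58,"Left Putamen","GM"
59,"Right Thalamus Proper","GM"
60,"Left Thalamus Proper","GM"
61,"Right Ventral DC","GM"
62,"Left Ventral DC","GM"
71,"Cerebellar Vermal Lobules I-V","GM"
72,"Cerebellar Vermal Lobules VI-VII","GM"
73,"Cerebellar Vermal Lobules VIII-X","GM"
75,"Left Basal Forebrain","GM"
76,"Right Basal Forebrain","GM"
100,"Right Anterior Cingulate Gyrus","GM"
101,"Left Anterior Cingulate Gyrus","GM"
102,"Right Anterior Insula","GM"
103,"Left Anterior Insula","GM"
104,"Right Anterior Orbital Gyrus","GM"
105,"Left Anterior Orbital Gyrus","GM"
106,"Right Angular Gyrus","GM"
107,"Left Angular Gyrus","GM"
108,"Right Calcarine Cortex","GM"
109,"Left Calcarine Cortex","GM"
112,"Right Central Operculum","GM"
113,"Left Central Operculum","GM"
114,"Right Cuneus","GM"
115,"Left Cuneus","GM"
116,"Right Entorhinal Area","GM"
117,"Left Entorhinal Area","GM"
118,"Right Frontal Operculum","GM"
119,"Left Frontal Operculum","GM"
120,"Right Frontal Pole","GM"
121,"Left Frontal Pole","GM"
122,"Right Fusiform Gyrus","GM"
123,"Left Fusiform Gyrus","GM"
124,"Right Gyrus Rectus","GM"
125,"Left Gyrus Rectus","GM"
128,"Right Inferior Occipital Gyrus","GM"
129,"Left Inferior Occipital Gyrus","GM"
132,"Right Inferior Temporal Gyrus","GM"
133,"Left Inferior Temporal Gyrus","GM"
134,"Right Lingual Gyrus","GM"
135,"Left Lingual Gyrus","GM"
136,"Right Lateral Orbital Gyrus","GM"
137,"Left Lateral Orbital Gyrus","GM"
138,"Right Middle Cingulate Gyrus","GM"
139,"Left Middle Cingulate Gyrus","GM"
140,"Right Medial Frontal Cortex","GM"
141,"Left Medial Frontal Cortex","GM"
142,"Right Middle Frontal Gyrus","GM"
143,"Left Middle Frontal Gyrus","GM"
144,"Right Middle Occipital Gyrus","GM"
145,"Left Middle Occipital Gyrus","GM"
146,"Right Medial Orbital Gyrus","GM"
147,"Left Medial Orbital Gyrus","GM"
148,"Right Postcentral Gyrus Medial Segment","GM"
149,"Left Postcentral Gyrus Medial Segment","GM"
150,"Right Precentral Gyrus Medial Segment","GM"
151,"Left Precentral Gyrus Medial Segment","GM"
152,"Right Superior Frontal Gyrus Medial Segment","GM"
153,"Left Superior Frontal Gyrus Medial Segment","GM"
154,"Right Middle Temporal Gyrus","GM"
155,"Left Middle Temporal Gyrus","GM"
156,"Right Occipital Pole","GM"
157,"Left Occipital Pole","GM"
160,"Right Occipital Fusiform Gyrus","GM"
161,"Left Occipital Fusiform Gyrus","GM"
162,"Right Opercular Part of the Inferior Frontal Gyrus","GM"
163,"Left Opercular Part of the Inferior Frontal Gyrus","GM"
164,"Right Orbital Part of the Inferior Frontal Gyrus","GM"
165,"Left Orbital Part of the Inferior Frontal Gyrus","GM"
166,"Right Posterior Cingulate Gyrus","GM"
167,"Left Posterior Cingulate Gyrus","GM"
168,"Right Precuneus","GM"
169,"Left Precuneus","GM"
170,"Right Parahippocampal Gyrus","GM"
171,"Left Parahippocampal Gyrus","GM"
172,"Right Posterior Insula","GM"
173,"Left Posterior Insula","GM"
174,"Right Parietal Operculum","GM"
175,"Left Parietal Operculum","GM"
176,"Right Postcentral Gyrus","GM"
177,"Left Postcentral Gyrus","GM"
178,"Right Posterior Orbital Gyrus","GM"
179,"Left Posterior Orbital Gyrus","GM"
180,"Right Planum Polare","GM"
181,"Left Planum Polare","GM"
182,"Right Precentral Gyrus","GM"
183,"Left Precentral Gyrus","GM"
184,"Right Planum Temporale","GM"
185,"Left Planum Temporale","GM"
186,"Right Subcallosal Area","GM"
187,"Left Subcallosal Area","GM"
190,"Right Superior Frontal Gyrus","GM"
191,"Left Superior Frontal Gyrus","GM"
192,"Right Supplementary Motor Cortex","GM"
193,"Left Supplementary Motor Cortex","GM"
194,"Right Supramarginal Gyrus","GM"
195,"Left Supramarginal Gyrus","GM"
196,"Right Superior Occipital Gyrus","GM"
197,"Left Superior Occipital Gyrus","GM"
198,"Right Superior Parietal Lobule","GM"
199,"Left Superior Parietal Lobule","GM"
200,"Right Superior Temporal Gyrus","GM"
201,"Left Superior Temporal Gyrus","GM"
202,"Right Temporal Pole","GM"
203,"Left Temporal Pole","GM"
204,"Right Triangular Part of the Inferior Frontal Gyrus","GM"
205,"Left Triangular Part of the Inferior Frontal Gyrus","GM"
206,"Right Transverse Temporal Gyrus","GM"
207,"Left Transverse Temporal Gyrus","GM"
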