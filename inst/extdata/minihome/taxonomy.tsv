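feature_id	lineage
Soilgenus001	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus001
Soilgenus002	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus002
Soilgenus003	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus003
Soilgenus004	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus004
Soilgenus005	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus005
Soilgenus006	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus006
Soilgenus007	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus007
Soilgenus008	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus008
Soilgenus009	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus009
Soilgenus010	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus010
Soilgenus011	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus011
Soilgenus012	d__Bacteria;p__;c__;o__;f__Soilaceae;g__Soilgenus012
Staphylococcus	d__Bacteria;p__;c__;o__;f__Staphylococcaceae;g__Staphylococcus
Streptococcus	d__Bacteria;p__;c__;o__;f__Streptococcaceae;g__Streptococcus
Cutibacterium	d__Bacteria;p__;c__;o__;f__Propionibacteriaceae;g__Cutibacterium
Corynebacterium	d__Bacteria;p__;c__;o__;f__Corynebacteriaceae;g__Corynebacterium
Escherichia	d__Bacteria;p__;c__;o__;f__Enterobacteriaceae;g__Escherichia
Humangenus001	d__Bacteria;p__;c__;o__;f__Humanaceae;g__Humangenus001
Humangenus002	d__Bacteria;p__;c__;o__;f__Humanaceae;g__Humangenus002
Humangenus003	d__Bacteria;p__;c__;o__;f__Humanaceae;g__Humangenus003
Outdoorgenus001	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus001
Outdoorgenus002	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus002
Outdoorgenus003	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus003
Outdoorgenus004	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus004
Outdoorgenus005	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus005
Outdoorgenus006	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus006
Outdoorgenus007	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus007
Outdoorgenus008	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus008
Outdoorgenus009	d__Bacteria;p__;c__;o__;f__Outdooraceae;g__Outdoorgenus009
Homegenus001	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus001
Homegenus002	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus002
Homegenus003	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus003
Homegenus004	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus004
Homegenus005	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus005
Homegenus006	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus006
Homegenus007	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus007
Homegenus008	d__Bacteria;p__;c__;o__;f__Homeaceae;g__Homegenus008
Contamgenus001	d__Bacteria;p__;c__;o__;f__Contamaceae;g__Contamgenus001
Contamgenus002	d__Bacteria;p__;c__;o__;f__Contamaceae;g__Contamgenus002
Contamgenus003	d__Bacteria;p__;c__;o__;f__Contamaceae;g__Contamgenus003
Contamgenus004	d__Bacteria;p__;c__;o__;f__Contamaceae;g__Contamgenus004
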