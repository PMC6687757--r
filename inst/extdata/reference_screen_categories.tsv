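class	target	basal_class	suppression_category
rab	Rab1A	fragments_alone	not_scored
rab	Rab2A	fragments_alone	not_scored
rab	Rab1B	no_effect	non_suppressive
rab	Rab4A	no_effect	non_suppressive
rab	Rab6	no_effect	both
rab	Rab6A	no_effect	both
rab	Rab6A'	no_effect	both
rab	Rab8A	no_effect	non_suppressive
rab	Rab10	no_effect	non_suppressive
rab	Rab11A	no_effect	ZW10_only
rab	Rab14	no_effect	non_suppressive
rab	Rab22A	no_effect	both
rab	Rab27A	no_effect	both
rab	Rab29	no_effect	ZW10_only
rab	Rab30	no_effect	non_suppressive
rab	Rab33B	no_effect	ZW10_only
rab	Rab34	no_effect	non_suppressive
rab	Rab38	no_effect	non_suppressive
rab	Rab39A	no_effect	both
rab	Rab43	no_effect	non_suppressive
kif	Kif4A	fragments_alone	not_scored
kif	Kif10	fragments_alone	non_suppressive
kif	Kif11	fragments_alone	non_suppressive
kif	Kif12	fragments_alone	non_suppressive
kif	Kif14	fragments_alone	ZW10_only
kif	Kif15	fragments_alone	not_scored
kif	Kif21A	fragments_alone	non_suppressive
kif	Kif24	fragments_alone	non_suppressive
kif	Kif26A	fragments_alone	non_suppressive
kif	Kif26B	fragments_alone	non_suppressive
kif	Kif20A	stretched	not_scored
kif	Kif23	stretched	not_scored
kif	Kif18A	toxic	non_suppressive
kif	Kif1A	no_effect	not_scored
kif	Kif1B	no_effect	non_suppressive
kif	Kif1C	no_effect	non_suppressive
kif	Kif2A	no_effect	non_suppressive
kif	Kif2B	no_effect	non_suppressive
kif	Kif2C	no_effect	ZW10_only
kif	Kif3A	no_effect	ZW10_only
kif	Kif3B	no_effect	non_suppressive
kif	Kif3C	no_effect	not_scored
kif	Kif4B	no_effect	ZW10_only
kif	Kif5A	no_effect	ZW10_only
kif	Kif5B	no_effect	non_suppressive
kif	Kif5C	no_effect	non_suppressive
kif	Kif6	no_effect	ZW10_only
kif	Kif7	no_effect	ZW10_only
kif	Kif9	no_effect	ZW10_only
kif	Kif13A	no_effect	not_scored
kif	Kif13B	no_effect	non_suppressive
kif	Kif16A	no_effect	non_suppressive
kif	Kif16B	no_effect	non_suppressive
kif	Kif17	no_effect	ZW10_only
kif	Kif18B	no_effect	non_suppressive
kif	Kif19	no_effect	non_suppressive
kif	Kif20B	no_effect	non_suppressive
kif	Kif21B	no_effect	non_suppressive
kif	Kif22	no_effect	not_scored
kif	Kif25	no_effect	both
kif	Kif27	no_effect	non_suppressive
kif	KifC1	no_effect	not_scored
kif	KifC2	no_effect	ZW10_only
kif	KifC3	no_effect	both
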