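# Default prokaryotic transcription-factor Pfam domain model list
# (40 DNA-binding-domain models, 25 effector/receiver "non-DBD" models).
# This is a RECONSTRUCTED, editable default assembled from well-known
# curated TF-domain collections; supply your own list for a real study.
model	pfam	category
HTH_1	PF00126	DBD
HTH_3	PF01381	DBD
HTH_6	PF01418	DBD
HTH_AraC	PF00165	DBD
LacI	PF00356	DBD
GntR	PF00392	DBD
TetR_N	PF00440	DBD
MarR	PF01047	DBD
Crp	PF00325	DBD
Fur	PF01475	DBD
MerR	PF00376	DBD
DeoR	PF00455	DBD
IclR	PF01614	DBD
PadR	PF03551	DBD
Rrf2	PF02082	DBD
HxlR	PF01638	DBD
Penicillinase_R	PF03965	DBD
Trp_repressor	PF01371	DBD
LytTR	PF04397	DBD
Arg_repressor	PF01316	DBD
Fe_dep_repress	PF01325	DBD
MetJ	PF01340	DBD
RHH_1	PF01402	DBD
TrmB	PF01978	DBD
GerE	PF00196	DBD
HTH_5	PF01022	DBD
Trans_reg_C	PF00486	DBD
HrcA	PF01628	DBD
LexA_DNA_bind	PF01726	DBD
Mga	PF05043	DBD
WhiB	PF02467	DBD
BolA	PF01722	DBD
FlhD	PF05247	DBD
FlhC	PF05280	DBD
HTH_8	PF02954	DBD
PaaX	PF07848	DBD
NrdR	PF03477	DBD
Crl	PF07417	DBD
ComK	PF06338	DBD
ROK	PF00480	DBD
Response_reg	PF00072	non-DBD
Aldedh	PF00171	non-DBD
Sugar-bind	PF04198	non-DBD
UTRA	PF07702	non-DBD
TOBE	PF03459	non-DBD
Peptidase_S24	PF00717	non-DBD
Pro_dh	PF01619	non-DBD
LysR_substrate	PF03466	non-DBD
PAS	PF00989	non-DBD
GAF	PF01590	non-DBD
CBS	PF00571	non-DBD
cNMP_binding	PF00027	non-DBD
ACT	PF01842	non-DBD
Autoind_bind	PF03472	non-DBD
SIS	PF01380	non-DBD
Peripla_BP_1	PF00532	non-DBD
Sigma54_activat	PF00158	non-DBD
FCD	PF07729	non-DBD
B12-binding	PF02310	non-DBD
TrkA_N	PF02254	non-DBD
ANTAR	PF03861	non-DBD
PhoU	PF01895	non-DBD
AsnC_trans_reg	PF01037	non-DBD
Ada_Zn_binding	PF02805	non-DBD
HAMP	PF00672	non-DBD
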