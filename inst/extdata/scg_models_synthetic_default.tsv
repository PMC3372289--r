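# Default universal single-copy-gene Pfam model list (53 models), mostly
# translation-machinery families assumed present once per prokaryotic
# genome. This is a RECONSTRUCTED, editable default; supply your own list
# for a real study.
model	pfam
Ribosomal_S2	PF00318
Ribosomal_S3_C	PF00189
Ribosomal_S4	PF00163
Ribosomal_S5	PF00333
Ribosomal_S6	PF01250
Ribosomal_S7	PF00177
Ribosomal_S8	PF00410
Ribosomal_S9	PF00380
Ribosomal_S10	PF00338
Ribosomal_S11	PF00411
Ribosomal_S12	PF00164
Ribosomal_S13	PF00416
Ribosomal_S15	PF00312
Ribosomal_S16	PF00886
Ribosomal_S17	PF00366
Ribosomal_S19	PF00203
Ribosomal_S20p	PF01649
Ribosomal_L1	PF00687
Ribosomal_L2	PF00181
Ribosomal_L3	PF00297
Ribosomal_L4	PF00573
Ribosomal_L5	PF00281
Ribosomal_L6	PF00347
Ribosomal_L9_N	PF01281
Ribosomal_L10	PF00466
Ribosomal_L11	PF00298
Ribosomal_L13	PF00572
Ribosomal_L14	PF00238
Ribosomal_L15	PF00828
Ribosomal_L16	PF00252
Ribosomal_L17	PF01196
Ribosomal_L18p	PF00861
Ribosomal_L19	PF01245
Ribosomal_L20	PF00453
Ribosomal_L21p	PF00829
Ribosomal_L22	PF00237
Ribosomal_L23	PF00276
Ribosomal_L27	PF01016
Ribosomal_L28	PF00830
Ribosomal_L29	PF00831
GTP_EFTU	PF00009
IF-2	PF04760
IF3_C	PF00707
SRP54	PF00448
SecY	PF00344
SecE	PF00584
RNA_pol_A	PF00623
RNA_pol_Rpb2_6	PF00562
tRNA-synt_1	PF00133
tRNA-synt_1c	PF00749
tRNA-synt_2b	PF00587
PGK	PF00162
RecA	PF00154
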