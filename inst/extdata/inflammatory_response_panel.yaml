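name: inflammatory-response-84
targets:
- CXCL2
- CXCL3
- BCL6
- CXCL5
- FASLG
- CRP
- CCL21
- CXCR1
- CD40
- IL22
- CCL11
- CXCL1
- CCL2
- CCL16
- IL17A
- IL1B
- IL23A
- CCR2
- IL23R
- CCL24
- CCL22
- ITGB2
- CXCL9
- CCR1
- C3AR1
- CXCL10
- NOS2
- CD40LG
- LY96
- TNFSF14
- CCR7
- CSF1
- CCL13
- IL1RN
- CCL19
- CEBPB
- IL1A
- LTA
- TLR5
- CCL5
- CCL23
- IRG01
- IRG02
- IRG03
- IRG04
- IRG05
- IRG06
- IRG07
- IRG08
- IRG09
- IRG10
- IRG11
- IRG12
- IRG13
- IRG14
- IRG15
- IRG16
- IRG17
- IRG18
- IRG19
- IRG20
- IRG21
- IRG22
- IRG23
- IRG24
- IRG25
- IRG26
- IRG27
- IRG28
- IRG29
- IRG30
- IRG31
- IRG32
- IRG33
- IRG34
- IRG35
- IRG36
- IRG37
- IRG38
- IRG39
- IRG40
- IRG41
- IRG42
- IRG43
housekeeping:
- ACTB
- B2M
- GAPDH
- HPRT1
- RPLP0
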