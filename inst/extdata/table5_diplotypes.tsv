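gene	sample	platform	reference	call
CFTR	HG001	R9.4.1	- (*WT/*WT)	*WT/*WT
CFTR	HG001	R10.4.1	- (*WT/*WT)	*WT/*WT
CFTR	HG01190	R10.4.1	-	*WT/*WT
CFTR	NA19785	R10.4.1	-	*WT/*WT
COMT	HG001	R9.4.1	-	*Met/*ValA
COMT	HG001	R10.4.1	-	*Met/*ValA
COMT	HG01190	R10.4.1	-	*Met/*ValA
COMT	NA19785	R10.4.1	-	*Met/*ValB
CYP1A2	HG001	R9.4.1	*1F/*1F	*1M/*1M
CYP1A2	HG001	R10.4.1	*1F/*1F	*1M/*1M
CYP1A2	HG01190	R10.4.1	*1A/*1A	*1B/*1B
CYP1A2	NA19785	R10.4.1	*1L/*1L	*1L/*1L
CYP2A13	HG001	R9.4.1	*1A/*1A	*1/*1
CYP2A13	HG001	R10.4.1	*1A/*1A	*1/*1
CYP2A13	HG01190	R10.4.1	*1A/*1A	*1/*1
CYP2A13	NA19785	R10.4.1	-	*1/*1
CYP2A6	HG001	R9.4.1	*1/*1	*1+*1/*12
CYP2A6	HG001	R10.4.1	*1/*1	*1+*1/*12
CYP2A6	HG01190	R10.4.1	*1/*1	*1/*1
CYP2A6	NA19785	R10.4.1	*1/*1	*1/*1
CYP2B6	HG001	R9.4.1	*1/*1	*1/*1
CYP2B6	HG001	R10.4.1	*1/*1	*1/*1
CYP2B6	HG01190	R10.4.1	*1(*5)/*1(*27)	*1/*5
CYP2B6	NA19785	R10.4.1	*1/*1	*1/*5
CYP2C19	HG001	R9.4.1	*1/*2	*1/*2
CYP2C19	HG001	R10.4.1	*1/*2	*1/*2
CYP2C19	HG01190	R10.4.1	*1/*2	*1/*2
CYP2C19	NA19785	R10.4.1	*1/*1	*1/*1
CYP2C8	HG001	R9.4.1	*1/*3	*3/*5
CYP2C8	HG001	R10.4.1	*1/*3	*1/*3
CYP2C8	HG01190	R10.4.1	*1/*3	*1/*3
CYP2C8	NA19785	R10.4.1	*1/*1	*1/*1
CYP2C9	HG001	R9.4.1	*1/*2	*1/*2
CYP2C9	HG001	R10.4.1	*1/*2	*1/*2
CYP2C9	HG01190	R10.4.1	*2/*61	*1/*61
CYP2C9	NA19785	R10.4.1	*1/*1	*1/*1
CYP2D6	HG001	R9.4.1	*3/*4+*68	*3 + *82/*4 +*132
CYP2D6	HG001	R10.4.1	*3/*4+*68	*4N.ALDY/*10+*82
CYP2D6	HG01190	R10.4.1	*4/*5	*4/*4
CYP2D6	NA19785	R10.4.1	*1/*2+*13	*2/*13
CYP2E1	HG001	R9.4.1	no consensus (*5)/*7	*1/*5A_7A_1B
CYP2E1	HG001	R10.4.1	no consensus (*5)/*7	*1/*5A_7A_1B
CYP2E1	HG01190	R10.4.1	*1/*7	*1/*7
CYP2E1	NA19785	R10.4.1	*7/*7	*4/*5
CYP2J2	HG001	R9.4.1	*1/*1	*1/*1
CYP2J2	HG001	R10.4.1	*1/*1	*1/*1
CYP2J2	HG01190	R10.4.1	*1/*7	*1/*7
CYP2J2	NA19785	R10.4.1	-	*1/*1
CYP3A4	HG001	R9.4.1	*1/*1	*1/*1
CYP3A4	HG001	R10.4.1	*1/*1	*1/*1
CYP3A4	HG01190	R10.4.1	*1/*1B	*36/*36
CYP3A4	NA19785	R10.4.1	*1/*1	*1/*36
CYP3A5	HG001	R9.4.1	*3/*3	*3/*3
CYP3A5	HG001	R10.4.1	*3/*3	*3/*3
CYP3A5	HG01190	R10.4.1	*1/*1	*1/*1
CYP3A5	NA19785	R10.4.1	*1/*3	*1/*3
CYP4F2	HG001	R9.4.1	*1/*1	*1/*1
CYP4F2	HG001	R10.4.1	*1/*1	*1/*1
CYP4F2	HG01190	R10.4.1	*1/*3	*1/*3
CYP4F2	NA19785	R10.4.1	*3/*3	*3/*3
DPYD	HG001	R9.4.1	*1/(*4)	*4/*5
DPYD	HG001	R10.4.1	*1/(*4)	*4/*5
DPYD	HG01190	R10.4.1	*1/*9	*1/*9
DPYD	NA19785	R10.4.1	*1/*1	*1/*1
G6PD	HG001	R9.4.1	NEG	*B/*B
G6PD	HG001	R10.4.1	NEG	*B/*B
G6PD	HG01190	R10.4.1	NEG	*B/*B
G6PD	NA19785	R10.4.1	NEG	*B/*B
GSTP1	HG001	R9.4.1	*A/*C; *B/*D	*A/*C
GSTP1	HG001	R10.4.1	*A/*C; *B/*D	*A/*C
GSTP1	HG01190	R10.4.1	*A/*B	*A/*B
GSTP1	NA19785	R10.4.1	*A/*B	*A/*B
NAT2	HG001	R9.4.1	*4/*5	*4/*5
NAT2	HG001	R10.4.1	*4/*5	*4/*5
NAT2	HG01190	R10.4.1	*4/*4	*4/*4
NAT2	NA19785	R10.4.1	no consensus	*7/*7 (curated: *7/*12)
NUDT15	HG001	R9.4.1	- (*1/*1)	*1/*1
NUDT15	HG001	R10.4.1	- (*1/*1)	*1/*1
NUDT15	HG01190	R10.4.1	- (*1/*1)	*1/*1
NUDT15	NA19785	R10.4.1	- (*1/*1)	*1/*1
SLCO1B1	HG001	R9.4.1	*1/*15	*1/*15
SLCO1B1	HG001	R10.4.1	*1/*15	*1/*15
SLCO1B1	HG01190	R10.4.1	*1/*1	*1/*1
SLCO1B1	NA19785	R10.4.1	*1/*1	*1/*37
TPMT	HG001	R9.4.1	*1/*1	*1/*1
TPMT	HG001	R10.4.1	*1/*1	*1/*1
TPMT	HG01190	R10.4.1	*1/*1	*1/*1
TPMT	NA19785	R10.4.1	*1/*1	*1/*1
UGT1A1	HG001	R9.4.1	*1/*28	*60_80/*112
UGT1A1	HG001	R10.4.1	*1/*28	*1/*28_60_80_93
UGT1A1	HG01190	R10.4.1	no consensus (*37)/*60	*1/*60_80 (curated: *1/*37_60_80)
UGT1A1	NA19785	R10.4.1	no consensus	*1/*28_60_80_93
VKORC1	HG001	R9.4.1	H1/(H9)	*H1/*H8
VKORC1	HG001	R10.4.1	H1/(H9)	*H1/*H9
VKORC1	HG01190	R10.4.1	*H7/*H7	*H7/*H7
VKORC1	NA19785	R10.4.1	*H1/*H1	*H1/*H1
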