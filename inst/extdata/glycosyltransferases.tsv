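gene	nj_call	nj_direction	ml_call	ml_direction	homolog	homolog_lgt	asterisk_note
Msp_0039	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	None		FALSE
Msp_0042	LGT	Bacteria->Archaea	LGT	DU	None		FALSE
Msp_0044	LGT	DU	LGT	DU	None		FALSE
Msp_0045	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0049	Non-LGT	N/A	N/A	N/A	None		TRUE
Msp_0051	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0052	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0053	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0054	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0055	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	None		FALSE
Msp_0056	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0057	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0080	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0101	LGT	Archaea->Bacteria	Non-LGT	N/A	Msm_0836	Non-LGT	FALSE
Msp_0203	LGT	DU	LGT	DU	None		FALSE
Msp_0206	LGT	DU	LGT	DU	Msm_1329	LGT	FALSE
Msp_0207	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	Msm_1330	LGT	FALSE
Msp_0212	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0215	LGT	DU	LGT	DU	None		FALSE
Msp_0218	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	None		FALSE
Msp_0220	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0441	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	None		FALSE
Msp_0442	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	Msm_1594	LGT	FALSE
Msp_0492	LGT	DU	LGT	N/A	Msm_1313	Non-LGT	FALSE
Msp_0493	LGT	Bacteria->Archaea	LGT	Bacteria->Archaea	None		FALSE
Msp_0495	LGT	DU	LGT	DU	None		FALSE
Msp_0496	LGT	DU	LGT	DU	None		TRUE
Msp_0500	LGT	DU	LGT	DU	Msm_1312	LGT	TRUE
Msp_0538	LGT	DU	LGT	DU	None		FALSE
Msp_0541	Non-LGT	N/A	N/A	N/A	Msm_1623	Non-LGT	FALSE
Msp_0645	Non-LGT	N/A	N/A	N/A	Msm_0423	Non-LGT	FALSE
Msp_0989	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_0991	Non-LGT	N/A	N/A	N/A	None		FALSE
Msp_1087	Non-LGT	N/A	N/A	N/A	None		FALSE
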