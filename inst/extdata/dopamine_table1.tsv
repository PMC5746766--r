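calculated_cm-1	measured_cm-1	assignment
381	393	CH wagging, ring deformation
577	593	CH in-plane ring deformation
622	635	CH wagging; aliphatic chain C-C vibrations
744	750	CH out-of-plane; ring deformation (two band response)
782	795	CH out-of-plane; ring deformation (two band response)
934	931	NH twisting
961	962	NH twisting; CH wagging; ring deformation
1029		CH wagging
1060		C-C-N stretching; CH wagging
1123	1117	CH twisting; NH twisting; CN stretching
1156	1148	OH rocking; CH aromatic rocking; weak ring breathing; CH wagging
	1209	CO stretching
1294	1285	Ring breathing; CH aromatic rocking; CH twisting
1321		Ring breathing; CH aromatic in-plane rocking; CH twisting
1355		Ring deformation; OH scissoring; CH twisting
1387		CH wagging; NH twisting
1466	1455	CH scissoring
1615	1617	Ring deformation, OH scissoring
1631		NH2 scissoring
1634		Benzene ring deformation
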