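site_group	peptide_sequence	composition_label	charges	isotopologue_cap
I_1	QIPLCANLVPVPITNATLDR	N4H5S2	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N4H5S2F1	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N4H5S1	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N5H6S3	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N5H6S3F1	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N5H6S2	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N5H6S2F1	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N5H6S1	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N6H7S4	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N6H7S4F1	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N6H7S3	3;4	NA
I_1	QIPLCANLVPVPITNATLDR	N6H7S2	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N4H5S2	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N4H5S2F1	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N4H5S1	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N5H6S3	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N5H6S3F1	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N5H6S2	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N5H6S2F1	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N5H6S1	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N6H7S4	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N6H7S4F1	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N6H7S3	3;4	NA
I_12	QIPLCANLVPVPITNATLDQITGK	N6H7S2	3;4	NA
II_12	NEEYNK	N4H5S2	3;4	NA
II_12	NEEYNK	N4H5S1	3;4	NA
II_12	NEEYNK	N5H6S3	3;4	NA
II_12	NEEYNK	N5H6S3F1	3;4	NA
II_12	NEEYNK	N5H6S2	3;4	NA
II_12	NEEYNK	N5H6S1	3;4	NA
II_12	NEEYNK	N6H7S4	3;4	NA
II_12	NEEYNK	N6H7S3	3;4	NA
III_12	SVQEIQATFFYFTPNK	N4H5S2	3;4	NA
III_12	SVQEIQATFFYFTPNK	N4H5S1	3;4	NA
III_12	SVQEIQATFFYFTPNK	N5H6S3	3;4	NA
III_12	SVQEIQATFFYFTPNK	N5H6S3F1	3;4	NA
III_12	SVQEIQATFFYFTPNK	N5H6S2	3;4	NA
III_12	SVQEIQATFFYFTPNK	N5H6S1	3;4	NA
III_12	SVQEIQATFFYFTPNK	N6H7S4	3;4	NA
III_12	SVQEIQATFFYFTPNK	N6H7S4F1	3;4	NA
III_12	SVQEIQATFFYFTPNK	N6H7S3	3;4	NA
III_12	SVQEIQATFFYFTPNK	N6H7S2	3;4	NA
III_12	SVQEIQATFFYFTPNK	N6H7S1	3;4	NA
IV_1	QDQCIYNTTYLNVQR	N4H5S2	3;4	6
IV_1	QDQCIYNTTYLNVQR	N4H5S2F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N4H5S1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N5H6S3	3;4	6
IV_1	QDQCIYNTTYLNVQR	N5H6S3F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N5H6S2	3;4	6
IV_1	QDQCIYNTTYLNVQR	N5H6S2F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N5H6S1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S4	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S4F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S3	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S3F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S2	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S2F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N6H7S1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N7H8S4	3;4	6
IV_1	QDQCIYNTTYLNVQR	N7H8S4F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N7H8S3	3;4	6
IV_1	QDQCIYNTTYLNVQR	N7H8S3F1	3;4	6
IV_1	QDQCIYNTTYLNVQR	N7H8S2	3;4	6
IV_1	QDQCIYNTTYLNVQR	N7H8S1	3;4	6
V_1	ENGTISR	N5H6S3	3;4	NA
V_1	ENGTISR	N5H6S3F1	3;4	NA
V_1	ENGTISR	N5H6S2	3;4	NA
V_1	ENGTISR	N5H6S2F1	3;4	NA
V_1	ENGTISR	N6H7S4	3;4	NA
V_1	ENGTISR	N6H7S4F1	3;4	NA
V_1	ENGTISR	N6H7S3	3;4	NA
V_1	ENGTISR	N6H7S3F1	3;4	NA
V_1	ENGTISR	N6H7S2	3;4	NA
V_1	ENGTISR	N6H7S2F1	3;4	NA
V_1	ENGTISR	N7H8S4	3;4	NA
V_1	ENGTISR	N7H8S4F1	3;4	NA
V_1	ENGTISR	N7H8S3	3;4	NA
V_1	ENGTISR	N7H8S3F1	3;4	NA
V_1	ENGTISR	N7H8S2	3;4	NA
V_2	ENGTVSR	N4H5S2	3;4	NA
V_2	ENGTVSR	N4H5S1	3;4	NA
V_2	ENGTVSR	N5H6S3	3;4	NA
V_2	ENGTVSR	N5H6S3F1	3;4	NA
V_2	ENGTVSR	N5H6S2	3;4	NA
V_2	ENGTVSR	N5H6S1	3;4	NA
V_2	ENGTVSR	N6H7S4	3;4	NA
V_2	ENGTVSR	N6H7S4F1	3;4	NA
V_2	ENGTVSR	N6H7S4F2	3;4	NA
V_2	ENGTVSR	N6H7S3	3;4	NA
V_2	ENGTVSR	N6H7S3F1	3;4	NA
V_2	ENGTVSR	N6H7S2	3;4	NA
V_2	ENGTVSR	N7H8S4	3;4	NA
V_2	ENGTVSR	N7H8S4F1	3;4	NA
V_2	ENGTVSR	N7H8S4F2	3;4	NA
V_2	ENGTVSR	N7H8S3	3;4	NA
V_2	ENGTVSR	N7H8S2	3;4	NA
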