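gene	condition	true_fold	true_cv
G0001	NOR	1	0.30648491578176618
G0002	NOR	1	0.15288535964209587
G0003	NOR	1	0.24397079676855354
G0004	NOR	1	0.076543462555855507
G0005	NOR	1	0.13438310222700239
G0006	NOR	1	0.23964839011896399
G0007	NOR	1	0.18648327749688176
G0008	NOR	1	0.34076432748697694
G0009	NOR	1	0.10687081313226372
G0010	NOR	1	0.13701052446849643
G0011	NOR	1	0.099328556563705206
G0012	NOR	1	0.11387705460656435
G0013	NOR	1	0.16169531808700413
G0014	NOR	1	0.22596852385904642
G0015	NOR	1	0.059441353240981702
G0016	NOR	1	0.093022734927944842
G0017	NOR	1	0.13079118633177131
G0018	NOR	1	0.08753298530355097
G0019	NOR	1	0.29937055390328166
G0020	NOR	1	0.17793500269763174
G0021	NOR	1	0.34852224078495053
G0022	NOR	1	0.31319764151703566
G0023	NOR	1	0.28105651135556398
G0024	NOR	1	0.2749929915415123
G0025	NOR	1	0.15001920773647726
G0026	NOR	1	0.245213604811579
G0027	NOR	1	0.21258129868656395
G0028	NOR	1	0.25322975001763554
G0029	NOR	1	0.084930676850490272
G0030	NOR	1	0.13860670537687839
G0031	NOR	1	0.096972842444665724
G0032	NOR	1	0.29400403948966414
G0033	NOR	1	0.10402619950473309
G0034	NOR	1	0.12688280001748353
G0035	NOR	1	0.32210787378717209
G0036	NOR	1	0.10029150822665542
G0037	NOR	1	0.053834527637809521
G0038	NOR	1	0.10935636314097792
G0039	NOR	1	0.19566245290916412
G0040	NOR	1	0.28972705625928935
G0041	NOR	1	0.21355839921161535
G0042	NOR	1	0.27564791203476485
G0043	NOR	1	0.23205175825860352
G0044	NOR	1	0.081389681366272282
G0045	NOR	1	0.094694095221348112
G0046	NOR	1	0.071150053967721755
G0047	NOR	1	0.11869710679166019
G0048	NOR	1	0.14943846373353153
G0049	NOR	1	0.31944735930301249
G0050	NOR	1	0.28250827507581561
G0001	TUM	3	0.30648491578176618
G0002	TUM	-2.5	0.15288535964209587
G0003	TUM	1.8	0.24397079676855354
G0004	TUM	1	0.076543462555855507
G0005	TUM	1	0.13438310222700239
G0006	TUM	1	0.23964839011896399
G0007	TUM	1	0.18648327749688176
G0008	TUM	1	0.34076432748697694
G0009	TUM	1	0.10687081313226372
G0010	TUM	1	0.13701052446849643
G0011	TUM	1	0.099328556563705206
G0012	TUM	1	0.11387705460656435
G0013	TUM	1	0.16169531808700413
G0014	TUM	1	0.22596852385904642
G0015	TUM	1	0.059441353240981702
G0016	TUM	1	0.093022734927944842
G0017	TUM	1	0.13079118633177131
G0018	TUM	1	0.08753298530355097
G0019	TUM	1	0.29937055390328166
G0020	TUM	1	0.17793500269763174
G0021	TUM	1	0.34852224078495053
G0022	TUM	1	0.31319764151703566
G0023	TUM	1	0.28105651135556398
G0024	TUM	1	0.2749929915415123
G0025	TUM	1	0.15001920773647726
G0026	TUM	1	0.245213604811579
G0027	TUM	1	0.21258129868656395
G0028	TUM	1	0.25322975001763554
G0029	TUM	1	0.084930676850490272
G0030	TUM	1	0.13860670537687839
G0031	TUM	1	0.096972842444665724
G0032	TUM	1	0.29400403948966414
G0033	TUM	1	0.10402619950473309
G0034	TUM	1	0.12688280001748353
G0035	TUM	1	0.32210787378717209
G0036	TUM	1	0.10029150822665542
G0037	TUM	1	0.053834527637809521
G0038	TUM	1	0.10935636314097792
G0039	TUM	1	0.19566245290916412
G0040	TUM	1	0.28972705625928935
G0041	TUM	1	0.21355839921161535
G0042	TUM	1	0.27564791203476485
G0043	TUM	1	0.23205175825860352
G0044	TUM	1	0.081389681366272282
G0045	TUM	1	0.094694095221348112
G0046	TUM	1	0.071150053967721755
G0047	TUM	1	0.11869710679166019
G0048	TUM	1	0.14943846373353153
G0049	TUM	1	0.31944735930301249
G0050	TUM	1	0.28250827507581561
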