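species,suborder,mean_m,max_m
Anax_junius_syn,Anisoptera,857,2500
Libellula_luctuosa_syn,Anisoptera,702,1800
Libellula_pulchella_syn,Anisoptera,640,1500
Sympetrum_vicinum_syn,Anisoptera,530,1200
Leucorrhinia_frigida_syn,Anisoptera,458,900
Leucorrhinia_intacta_syn,Anisoptera,342,700
Pachydiplax_longipennis_syn,Anisoptera,203,540
Plathemis_lydia_syn,Anisoptera,118,310
Celithemis_elisa_syn,Anisoptera,96,NA
Ischnura_verticalis_syn,Zygoptera,264,610
Enallagma_ebrium_syn,Zygoptera,232,480
Enallagma_hageni_syn,Zygoptera,198,420
Lestes_disjunctus_syn,Zygoptera,161,390
Nehalennia_irene_syn,Zygoptera,134,260
Coenagrion_resolutum_syn,Zygoptera,102,NA
Chromagrion_conditum_syn,Zygoptera,88,170
Amphiagrion_saucium_syn,Zygoptera,57,120
Argia_moesta_syn,Zygoptera,42,95
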