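record_id	taxon	family	group	pattern	outgroup
KU350630.1	Callianassa_ceramica_J40715	Callianassidae	Axiidea	Ax2	FALSE
KU362925.1	Callianassa_ceramica	Callianassidae	Axiidea	Ax2	FALSE
NC_020025.1	Corallianassa_coutierei	Callianassidae	Axiidea	Ax1	FALSE
NC_020351.1	Nihonotrypaea_japonica	Callianassidae	Axiidea	Ax1	FALSE
NC_019610.1	Nihonotrypaea_thermophila	Callianassidae	Axiidea	Ax1	FALSE
NC_024651.1	Paraglypturus_tonganus	Callianassidae	Axiidea	Ax1	FALSE
KM501040.2	Trypaea_australiensis	Callianassidae	Axiidea	Ax2	FALSE
NC_019609.1	Neaxius_acanthus	Strahlaxiidae	Axiidea	Ax1	FALSE
NC_019608.1	Thalassina_kelanang	Thalassinidae	Gebiidea	Gr	FALSE
NC_019606.1	Austinogebia_edulis	Upogebiidae	Gebiidea	Up	FALSE
NC_019607.1	Upogebia_major	Upogebiidae	Gebiidea	Up	FALSE
NC_020023.1	Upogebia_pusilla	Upogebiidae	Gebiidea	Up	FALSE
NC_025943.1	Upogebia_yokoyai	Upogebiidae	Gebiidea	Up	FALSE
NC_018778.1	Alvinocaris_chelys	Alvinocarididae	Caridea	Gr	FALSE
NC_020313.1	Alvinocaris_longirostris	Alvinocarididae	Caridea	Gr	FALSE
NC_021971.1	Nautilocaris_saintlaurentae	Alvinocarididae	Caridea	Gr	FALSE
NC_020311.1	Opaepele_loihi	Alvinocarididae	Caridea	Gr	FALSE
NC_027116.1	Rimicaris_exoculata	Alvinocarididae	Caridea	Gr	FALSE
NC_020310.1	Rimicaris_kairei	Alvinocarididae	Caridea	Gr	FALSE
NC_014883.1	Alpheus_distinguendus	Alpheidae	Caridea	Ap1	FALSE
KP276147.1	Alpheus_lobidens	Alpheidae	Caridea	Ap2	FALSE
NC_024751.1	Caridina_gracilipes	Atyidae	Caridea	Gr	FALSE
KU726823.1	Caridina_cf_nilotica	Atyidae	Caridea	Gr	FALSE
NC_008413.1	Halocaridina_rubra	Atyidae	Caridea	Gr	FALSE
NC_023823.1	Neocaridina_denticulata	Atyidae	Caridea	Gr	FALSE
NC_027603.1	Paratya_australiensis	Atyidae	Caridea	Gr	FALSE
KM978918.1	Macrobrachium_bullatum	Palaemonidae	Caridea	Gr	FALSE
NC_012217.1	Macrobrachium_lanchesteri	Palaemonidae	Caridea	Gr	FALSE
NC_015073.1	Macrobrachium_nipponense	Palaemonidae	Caridea	Gr	FALSE
NC_006880.1	Macrobrachium_rosenbergii	Palaemonidae	Caridea	Gr	FALSE
NC_012566.1	Palaemon_carinicauda	Palaemonidae	Caridea	Pa	FALSE
NC_029240.1	Palaemon_gravieri	Palaemonidae	Caridea	Pa	FALSE
NC_027601.1	Palaemon_serenus	Palaemonidae	Caridea	Pa	FALSE
NC_017600.1	Acetes_chinensis	Sergestidae	Dendrobranchiata	Gr	TRUE
NC_012738.1	Farfantepenaeus_californiensis	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_009679.1	Fenneropenaeus_chinensis	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_026884.1	Fenneropenaeus_merguiensis	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_026885.1	Fenneropenaeus_penicillatus	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_009626.1	Litopenaeus_vannamei	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_007010.1	Marsupenaeus_japonicas	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_029457.1	Metapenaeopsis_dalei	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_026834.1	Metapenaeus_ensis	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_030277.1	Parapenaeopsis_hardwickii	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_002184.1	Penaeus_monodon	Penaeidae	Dendrobranchiata	Gr	TRUE
NC_030280.1	Solenocera_crassicornis	Solenoceridae	Dendrobranchiata	Gr	TRUE
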