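taxon_id,name,higher_group,eutrophic,oligotrophic,mesosaprobiont,endemic,saprobic_valence
anab_lemm,Anabaena lemmermannii,Cyanophyta,TRUE,FALSE,TRUE,FALSE,1.8
aste_form,Asterionella formosa,Bacillariophyta,TRUE,FALSE,TRUE,FALSE,1.85
cera_hiru,Ceratium hirundinella,Miozoa,FALSE,FALSE,TRUE,FALSE,1.6
dino_cyli,Dinobryon cylindricum,Ochrophyta,FALSE,FALSE,TRUE,FALSE,1.55
dino_dive,Dinobryon divergens,Ochrophyta,TRUE,FALSE,TRUE,FALSE,1.75
dino_soci,Dinobryon sociale,Ochrophyta,TRUE,FALSE,TRUE,FALSE,1.8
gymn_coer,Gymnodinium coeruleum,Miozoa,FALSE,TRUE,FALSE,FALSE,1.3
rhod_pusi,Rhodomonas pusilla,Cryptophyta,FALSE,TRUE,FALSE,FALSE,1.4
spir_spp,Spirogyra sp.,Chlorophyta,TRUE,FALSE,TRUE,FALSE,1.9
frag_radi,Fragilaria radians,Bacillariophyta,FALSE,FALSE,TRUE,FALSE,1.65
picopk,picoplankton,Cyanophyta,FALSE,TRUE,FALSE,FALSE,1.2
aspl_prio,Asplanchna priodonta,Rotifera,TRUE,FALSE,TRUE,FALSE,1.8
bosm_long,Bosmina longirostris,Cladocera,TRUE,FALSE,TRUE,FALSE,1.9
cycl_kole,Cyclops kolensis,Copepoda,FALSE,TRUE,FALSE,FALSE,1.35
daph_gale,Daphnia galeata,Cladocera,TRUE,FALSE,TRUE,FALSE,1.85
epis_baik,Epischura baikalensis,Copepoda,FALSE,TRUE,FALSE,TRUE,1.15
lept_kind,Leptodora kindtii,Cladocera,FALSE,FALSE,TRUE,FALSE,1.6
sync_gran,Synchaeta grandis,Rotifera,FALSE,FALSE,TRUE,FALSE,1.7
chae_pumi,Chaetocladiella pumila,Chlorophyta,FALSE,TRUE,FALSE,TRUE,1.1
clad_floc,Cladophora floccosa,Chlorophyta,FALSE,TRUE,FALSE,TRUE,1.2
drap_baic,Draparnaldioides baicalensis,Chlorophyta,FALSE,TRUE,FALSE,TRUE,1.15
drap_pilo,Draparnaldioides pilosa,Chlorophyta,FALSE,TRUE,FALSE,TRUE,1.2
tetr_cyli,Tetraspora cylindrica var. bullosa,Chlorophyta,FALSE,TRUE,FALSE,TRUE,1.1
schi_spp,Schizothrix sp.,Cyanophyta,FALSE,FALSE,TRUE,FALSE,1.8
cocc_plac,Cocconeis placentula,Bacillariophyta,TRUE,FALSE,TRUE,FALSE,1.75
cyma_sole,Cymatopleura solea,Bacillariophyta,TRUE,FALSE,TRUE,FALSE,2.0
didy_grun,Didymosphenia grunowii,Bacillariophyta,FALSE,TRUE,FALSE,TRUE,1.1
ency_pseu,Encyonema pseudoturgidum,Bacillariophyta,FALSE,TRUE,FALSE,TRUE,1.0
hann_baic,Hannaea baicalensis,Bacillariophyta,FALSE,TRUE,FALSE,TRUE,1.0
nitz_diss,Nitzschia dissipata,Bacillariophyta,TRUE,FALSE,TRUE,FALSE,2.0
nitz_rect,Nitzschia recta,Bacillariophyta,TRUE,FALSE,TRUE,FALSE,1.95
yasn_taty,Yasnitskya tatyanae,Bacillariophyta,FALSE,TRUE,FALSE,TRUE,1.0
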