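gene_id,origin_default,origin_brain,chromosome_order,chromosome
Zdbf2,PEG,PEG,1,1
Gpr1,PEG,PEG,2,1
Adam23,PEG,PEG,3,1
Sfmbt2,PEG,PEG,4,2
Commd1,MEG,MEG,5,2
Zrsr1,PEG,PEG,6,2
Mcts2,PEG,PEG,7,2
H13,MEG,MEG,8,2
Nnat,PEG,PEG,9,2
Blcap,MEG,MEG,10,2
Gatm,MEG,MEG,11,2
Nespas,PEG,PEG,12,2
Gnas,MEG,MEG,13,2
B3gnt2,MEG,MEG,14,2
Wt1,MEG,MEG,15,2
Zfp64,PEG,PEG,16,2
Jade1,MEG,MEG,17,3
Fkbp6,PEG,PEG,18,5
Magi2,MEG,MEG,19,5
Sgce,PEG,PEG,20,6
Peg10,PEG,PEG,21,6
Ppp1r9a,MEG,MEG,22,6
Pon1,MEG,MEG,23,6
Pon2,MEG,MEG,24,6
Pon3,MEG,MEG,25,6
Asb4,MEG,MEG,26,6
Calcr,MEG,MEG,27,6
Tfpi2,MEG,MEG,28,6
Cpa4,MEG,MEG,29,6
Mest,PEG,PEG,30,6
Copg2,MEG,MEG,31,6
Klf14,MEG,MEG,32,6
Nap1l5,PEG,PEG,33,6
Casd1,PEG,PEG,34,6
Cobl,MEG,MEG,35,6
Dlx5,MEG,MEG,36,6
Peg3,PEG,PEG,37,7
Usp29,PEG,PEG,38,7
Zim1,MEG,MEG,39,7
Zim2,MEG,MEG,40,7
Zim3,PEG,PEG,41,7
Zfp264,PEG,PEG,42,7
Mkrn3,PEG,PEG,43,7
Magel2,PEG,PEG,44,7
Ndn,PEG,PEG,45,7
Peg12,PEG,PEG,46,7
Snrpn,PEG,PEG,47,7
Snurf,PEG,PEG,48,7
Snhg14,PEG,PEG,49,7
Ipw,PEG,PEG,50,7
Ube3a,MEG,MEG,51,7
Atp10a,MEG,MEG,52,7
Inpp5f,PEG,PEG,53,7
Dhcr7,MEG,MEG,54,7
H19,MEG,MEG,55,7
Igf2,PEG,MEG,56,7
Igf2os,PEG,PEG,57,7
Ins2,PEG,PEG,58,7
Th,MEG,MEG,59,7
Ascl2,MEG,MEG,60,7
Tspan32,MEG,MEG,61,7
Cd81,MEG,MEG,62,7
Tssc4,MEG,MEG,63,7
Kcnq1,MEG,MEG,64,7
Kcnq1ot1,PEG,PEG,65,7
Kcnq1dn,MEG,MEG,66,7
Cdkn1c,MEG,MEG,67,7
Slc22a18,MEG,MEG,68,7
Slc22a21,MEG,MEG,69,7
Phlda2,MEG,MEG,70,7
Nap1l4,MEG,MEG,71,7
Osbpl5,MEG,MEG,72,7
Tnfrsf22,MEG,MEG,73,7
Tnfrsf23,MEG,MEG,74,7
Tnfrsf26,MEG,MEG,75,7
Ampd3,MEG,MEG,76,7
Ano1,MEG,MEG,77,7
Nctc1,MEG,MEG,78,7
Dlgap2,PEG,PEG,79,8
Kcnk9,MEG,MEG,80,8
Peg13,PEG,PEG,81,8
Trappc9,MEG,MEG,82,8
Ago2,MEG,MEG,83,8
Chrac1,MEG,MEG,84,8
Ptk2,MEG,MEG,85,8
Cdh15,MEG,MEG,86,8
Rasgrf1,PEG,PEG,87,9
A19,PEG,PEG,88,9
Gab1,PEG,PEG,89,9
Ntm,MEG,MEG,90,9
Plagl1,PEG,PEG,91,10
Hymai,PEG,PEG,92,10
Phactr2,MEG,MEG,93,10
Pde10a,MEG,MEG,94,10
Dcn,MEG,MEG,95,10
Grb10,MEG,PEG,96,11
Ddc,PEG,PEG,97,11
Adamts2,PEG,PEG,98,11
Begain,PEG,PEG,99,12
Dlk1,PEG,PEG,100,12
Rtl1,PEG,PEG,101,12
Dio3,PEG,PEG,102,12
Dio3os,MEG,MEG,103,12
Meg3,MEG,MEG,104,12
Rian,MEG,MEG,105,12
Mirg,MEG,MEG,106,12
Wars,MEG,MEG,107,12
Pde4d,PEG,PEG,108,13
Htr2a,MEG,MEG,109,14
Bmf,MEG,MEG,110,14
Slc38a4,PEG,PEG,111,15
Gm16299,MEG,MEG,112,15
Igf2r,MEG,MEG,113,17
Airn,PEG,PEG,114,17
Slc22a2,MEG,MEG,115,17
Slc22a3,MEG,MEG,116,17
Mas1,PEG,PEG,117,17
Impact,PEG,PEG,118,18
Ins1,PEG,PEG,119,19
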