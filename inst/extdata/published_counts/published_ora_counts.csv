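table_id,dataset,group,up_reg,ig_up,universe_genes,universe_tagged,printed_p,printed_q
mca_tissues,MCA adult tissues,Pancreas,2737,42,20534,95,1.57E-13,1.89E-12
mca_tissues,MCA adult tissues,Brain,3401,34,20534,95,4.43E-06,5.31E-05
mca_tissues,MCA adult tissues,Bladder,3183,29,20534,95,0.000168,0.002012
mca_tissues,MCA adult tissues,Uterus,2567,22,20534,95,0.002827,0.033919
mca_tissues,MCA adult tissues,Lung,1203,8,20534,95,0.192705,1
mca_tissues,MCA adult tissues,Ovary,2219,13,20534,95,0.223666,1
mca_tissues,MCA adult tissues,Kidney,1714,10,20534,95,0.268425,1
mca_tissues,MCA adult tissues,Liver,1739,8,20534,95,0.560145,1
mca_tissues,MCA adult tissues,Stomach,1821,7,20534,95,0.748590,1
mca_tissues,MCA adult tissues,Thymus,1805,6,20534,95,0.851579,1
mca_tissues,MCA adult tissues,Small Intestine,1719,5,20534,95,0.908008,1
mca_tissues,MCA adult tissues,Testis,5212,14,20534,95,0.995891,1
mca_tissues,MCA adult tissues,Bone Marrow,1095,2,20534,95,--,--
mca_tissues,MCA adult tissues,Mammary Gland Virgin,902,4,20534,95,--,--
mca_tissues,MCA adult tissues,Muscle,1127,4,20534,95,--,--
mca_tissues,MCA adult tissues,Peripheral Blood,1146,3,20534,95,--,--
mca_tissues,MCA adult tissues,Prostate,369,0,20534,95,--,--
mca_tissues,MCA adult tissues,Spleen,1501,1,20534,95,--,--
tm_tissues,Tabula Muris adult tissues,Diaphragm,416,19,20839,107,3.66E-13,4.75E-12
tm_tissues,Tabula Muris adult tissues,Limb Muscle,761,24,20839,107,6.32E-13,8.22E-12
tm_tissues,Tabula Muris adult tissues,Pancreas,4104,43,20839,107,8.31E-07,1.08E-05
tm_tissues,Tabula Muris adult tissues,Trachea,1979,25,20839,107,1.78E-05,0.0002
tm_tissues,Tabula Muris adult tissues,Brain (Non-Myeloid),3081,31,20839,107,0.0001,0.0016
tm_tissues,Tabula Muris adult tissues,Bladder,3338,31,20839,107,0.0005,0.0068
tm_tissues,Tabula Muris adult tissues,Fat,1263,12,20839,107,0.0286,0.3713
tm_tissues,Tabula Muris adult tissues,Heart,1108,10,20839,107,0.0585,0.7601
tm_tissues,Tabula Muris adult tissues,Mammary Gland,1826,12,20839,107,0.2264,1
tm_tissues,Tabula Muris adult tissues,Liver,1808,7,20839,107,0.8307,1
tm_tissues,Tabula Muris adult tissues,Aorta,3515,14,20839,107,0.8832,1
tm_tissues,Tabula Muris adult tissues,Tongue,4295,15,20839,107,0.9696,1
tm_tissues,Tabula Muris adult tissues,Large Intestine,4758,11,20839,107,0.9998,1
tm_tissues,Tabula Muris adult tissues,Brain (Myeloid),1024,5,20839,107,--,--
tm_tissues,Tabula Muris adult tissues,Kidney,584,3,20839,107,--,--
tm_tissues,Tabula Muris adult tissues,Lung,914,2,20839,107,--,--
tm_tissues,Tabula Muris adult tissues,Marrow,1957,5,20839,107,--,--
tm_tissues,Tabula Muris adult tissues,Skin,1612,4,20839,107,--,--
tm_tissues,Tabula Muris adult tissues,Spleen,625,1,20839,107,--,--
tm_tissues,Tabula Muris adult tissues,Thymus,678,4,20839,107,--,--
brain_lineage,Aging mouse brain cell classes,Neuroendocrine cells (NendC),3868,47,14498,85,2.12E-08,3.82E-07
brain_lineage,Aging mouse brain cell classes,Mature Neurons (all types) (mNEUR),2968,32,14498,85,0.0002,0.0035
brain_lineage,Aging mouse brain cell classes,Arachnoid barrier cells (ABC),2287,20,14498,85,0.0396,0.7120
brain_lineage,Aging mouse brain cell classes,Tanycytes (TNC),1279,12,14498,85,0.0692,1
brain_lineage,Aging mouse brain cell classes,Vascular and leptomeningeal cells (VLMC),1714,15,14498,85,0.0724,1
brain_lineage,Aging mouse brain cell classes,Oligodendrocyte precursor cells (OPC),1524,13,14498,85,0.1067,1
brain_lineage,Aging mouse brain cell classes,Pericytes (PC),1801,14,14498,85,0.1649,1
brain_lineage,Aging mouse brain cell classes,Olfactory ensheathing glia (OEG),1086,9,14498,85,0.1848,1
brain_lineage,Aging mouse brain cell classes,Oligodendrocytes (OLG),1183,9,14498,85,0.2561,1
brain_lineage,Aging mouse brain cell classes,Choroid plexus epithelial cells (CPC),2602,17,14498,85,0.3524,1
brain_lineage,Aging mouse brain cell classes,Hemoglobin-expressing vascular cells (Hb_VC),1798,11,14498,85,0.4889,1
brain_lineage,Aging mouse brain cell classes,Vascular smooth muscle cells (VSMC),3006,17,14498,85,0.6093,1
brain_lineage,Aging mouse brain cell classes,Astrocyte-restricted precursors (ARP),1445,8,14498,85,0.6214,1
brain_lineage,Aging mouse brain cell classes,Neural stem cells (NSC),1009,5,14498,85,0.7138,1
brain_lineage,Aging mouse brain cell classes,Ependymocytes (EPC),3233,17,14498,85,0.7346,1
brain_lineage,Aging mouse brain cell classes,Endothelial cells (EC),1455,7,14498,85,0.7619,1
brain_lineage,Aging mouse brain cell classes,Hypendymal cells (HypEPC),1525,6,14498,85,0.8946,1
brain_lineage,Aging mouse brain cell classes,Neuronal-restricted precursor (NRP),2339,10,14498,85,0.8979,1
brain_lineage,Aging mouse brain cell classes,Astrocytes (ASC),1384,4,14498,85,--,--
brain_lineage,Aging mouse brain cell classes,Dendritic cells (DC),1209,1,14498,85,--,--
brain_lineage,Aging mouse brain cell classes,Immature Neurons (ImmN),652,4,14498,85,--,--
brain_lineage,Aging mouse brain cell classes,Macrophages (MAC),1222,2,14498,85,--,--
brain_lineage,Aging mouse brain cell classes,Microglia (MG),1342,3,14498,85,--,--
brain_lineage,Aging mouse brain cell classes,Monocytes (MNC),947,2,14498,85,--,--
brain_lineage,Aging mouse brain cell classes,Neutrophils (NEUT),519,2,14498,85,--,--
mba_lineage,Mouse brain atlas cell lineages,Neurons,5710,44,19547,109,0.0081,0.0487
mba_lineage,Mouse brain atlas cell lineages,Vascular,2473,22,19547,109,0.0171,0.1029
mba_lineage,Mouse brain atlas cell lineages,Oligos,1587,11,19547,109,0.2701,1
mba_lineage,Mouse brain atlas cell lineages,Peripheral Glia,2820,16,19547,109,0.5117,1
mba_lineage,Mouse brain atlas cell lineages,Ependymal,3683,20,19547,109,0.5912,1
mba_lineage,Mouse brain atlas cell lineages,Immune,1564,7,19547,109,0.7787,1
mba_lineage,Mouse brain atlas cell lineages,Astrocytes,1539,4,19547,109,--,--
mba_regions,Mouse brain atlas neuron regions,Medulla,3147,45,18335,106,8.38E-10,1.26E-08
mba_regions,Mouse brain atlas neuron regions,Hypothalamus,1040,22,18335,106,9.81E-08,1.47E-06
mba_regions,Mouse brain atlas neuron regions,Pons,3581,44,18335,106,1.62E-07,2.43E-06
mba_regions,Mouse brain atlas neuron regions,Vent. Midbrain,1228,18,18335,106,0.0002,0.0034
mba_regions,Mouse brain atlas neuron regions,Vent. Striatum,689,8,18335,106,0.0463,0.6941
mba_regions,Mouse brain atlas neuron regions,Posterior Cortex,1090,9,18335,106,0.1788,1
mba_regions,Mouse brain atlas neuron regions,Enteric Nervous System,3885,26,18335,106,0.2311,1
mba_regions,Mouse brain atlas neuron regions,Sympathetic Nervous System,2804,18,18335,106,0.3535,1
mba_regions,Mouse brain atlas neuron regions,Anterior Cortex,979,6,18335,106,0.5016,1
mba_regions,Mouse brain atlas neuron regions,Dors. Midbrain,1045,6,18335,106,0.5663,1
mba_regions,Mouse brain atlas neuron regions,Thalamus,1441,8,18335,106,0.6000,1
mba_regions,Mouse brain atlas neuron regions,Hippocampus-CA1,1082,6,18335,106,0.6008,1
mba_regions,Mouse brain atlas neuron regions,Somatosensory Cortex,2121,11,18335,106,0.6943,1
mba_regions,Mouse brain atlas neuron regions,Dors. Striatum,1196,6,18335,106,0.6974,1
mba_regions,Mouse brain atlas neuron regions,Dorsal Root Ganglion,3607,16,18335,106,0.9088,1
mba_regions,Mouse brain atlas neuron regions,Middle Cortex,623,5,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Spinal Cord,972,5,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Amygdala,452,4,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Dentate Gyrus,796,4,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Hippocampus,631,4,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Olfactory Bulb,445,4,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Antero-Middle Cortex,646,3,18335,106,--,--
mba_regions,Mouse brain atlas neuron regions,Cerebellum,240,0,18335,106,--,--
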