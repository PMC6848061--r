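stimulation,region,group,mean_pct,sem_pct,n
whisker_pad,S1_S2,sham,0.89,0.08,18
whisker_pad,S1_S2,plion,0.60,0.07,13
whisker_pad,S1_S2,plion_minocycline,0.76,0.08,15
molar_pulp,S1,sham,0.27,0.05,13
molar_pulp,S1,plion,0.54,0.08,13
molar_pulp,S1,plion_minocycline,0.38,0.05,14
molar_pulp,S2_IOR,sham,0.21,0.04,13
molar_pulp,S2_IOR,plion,0.55,0.06,13
molar_pulp,S2_IOR,plion_minocycline,0.36,0.05,14
mentum_skin,S1,sham,0.36,0.05,7
mentum_skin,S1,plion,0.59,0.04,15
mentum_skin,S1,plion_minocycline,0.44,0.04,15
mentum_skin,S2_IOR,sham,0.17,0.07,7
mentum_skin,S2_IOR,plion,0.46,0.05,15
mentum_skin,S2_IOR,plion_minocycline,0.32,0.03,15
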