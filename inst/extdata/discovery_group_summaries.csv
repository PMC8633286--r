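peptide_id,protein_name,control_mean,control_sd,pd_mean,pd_sd,msa_mean,msa_sd,p_value,ratio_pd_vs_msa
GFYFSR,Insulin-like growth factor II,5.64E+06,6.45E+06,8.89E+06,8.98E+06,2.79E+07,4.64E+06,0.004,3.1
VQLSEFSPPGSR,Protocadherin Fat 2,1.78E+05,1.27E+05,4.55E+05,4.46E+05,2.06E+05,1.46E+05,0.008,2.2
DDDFTTWTQLAK,Protein O-linked-mannose beta-1.2-N-acetylglucosaminyltransferase 1,3.79E+05,2.80E+05,5.39E+05,2.93E+05,2.56E+05,1.88E+05,0.008,2.1
ALYYDLISSPDIHGTYK,Pigment epithelium-derived factor,1.38E+07,9.88E+06,1.21E+07,7.53E+06,2.35E+07,6.10E+06,0.008,1.9
HVLFGTVGVPEHTYR,Thy-1 membrane glycoprotein,7.85E+05,9.27E+05,5.63E+05,4.25E+05,1.76E+05,1.48E+05,0.013,3.2
FLDTGVVQSDR,Multiple epidermal growth factor-like domains protein 8,1.18E+06,3.74E+05,1.22E+06,7.37E+05,6.32E+05,4.95E+05,0.013,1.9
NVALVSGDTENAK,Extracellular matrix protein 1,1.07E+06,3.80E+05,1.38E+06,3.33E+05,8.43E+05,5.41E+05,0.013,1.6
LALFPDK,Neuroblastoma suppressor of tumorigenicity 1,5.92E+07,2.16E+07,3.14E+07,1.99E+07,7.18E+07,1.80E+07,0.013,2.3
VFNTPEGVPSAPSSLK,Neuronal cell adhesion molecule,4.89E+06,1.93E+06,6.20E+06,2.63E+06,4.01E+06,1.06E+06,0.013,1.5
SFPLSSEHAK,Cadherin-2,1.04E+05,1.24E+05,1.94E+05,1.58E+05,5.47E+04,5.48E+04,0.018,3.6
LTGISDPVTVK,Noelin,1.82E+05,2.04E+05,3.90E+05,3.00E+05,2.02E+05,1.88E+05,0.019,1.9
FEAFEEDR,Seizure 6-like protein 2,4.53E+05,8.52E+05,2.75E+06,3.24E+06,5.48E+05,9.32E+05,0.019,5.0
FLEQELETITIPDLR,Phospholipid transfer protein,1.13E+06,8.54E+05,6.05E+05,1.10E+06,1.25E+06,6.94E+05,0.019,2.1
LSPYVNYQFR,Neurofascin,1.18E+06,4.11E+05,8.67E+05,7.44E+05,1.58E+06,3.22E+05,0.019,1.8
VLEYLNQEK,Secretogranin-2,6.14E+06,3.04E+06,7.93E+06,5.34E+06,4.59E+06,1.19E+06,0.019,1.7
SYLEITPSR,Inter-alpha-trypsin inhibitor heavy chain H5,7.34E+05,3.47E+05,6.72E+05,2.89E+05,1.20E+06,2.57E+05,0.019,1.8
YGFIEGHVVIPR,CD44 antigen,3.84E+06,1.90E+06,2.72E+06,1.98E+06,7.34E+06,2.29E+06,0.019,2.7
VESLEQEAANER,Amyloid-beta precursor protein,6.46E+05,1.80E+06,1.28E+07,1.49E+07,5.64E+05,1.17E+06,0.026,22.7
NLLDLR,SLIT and NTRK-like protein 1,8.09E+04,1.12E+05,4.59E+05,3.48E+05,3.74E+04,3.53E+04,0.028,12.3
LTVFPDGTLEVR,Leucine-rich repeat and immunoglobulin-like domain-containing nogo receptor-interacting protein 1,5.92E+05,4.49E+05,6.86E+05,3.79E+05,3.20E+05,3.20E+05,0.028,2.1
AFQVWSDVTPLR,72 kDa type IV collagenase,2.99E+05,2.96E+05,3.08E+05,1.93E+05,1.50E+05,1.29E+05,0.028,2.1
AVVEVDESGTR,Plasma serine protease inhibitor,2.32E+05,3.13E+05,5.72E+05,3.81E+05,1.89E+05,2.09E+05,0.028,3.0
FPPEETLK,Carboxypeptidase E,1.25E+06,1.13E+06,8.31E+05,9.74E+05,2.06E+06,9.48E+05,0.028,2.5
LQAPVWEFK,Ceroid-lipofuscinosis neuronal protein 5,1.51E+06,6.12E+05,1.10E+06,8.80E+05,2.34E+06,1.44E+05,0.028,2.1
LFEELVR,Pyruvate kinase PKM,6.78E+06,3.51E+06,6.91E+06,1.07E+07,1.18E+07,5.81E+06,0.028,1.7
SQETGDLDVGGLQETDK,Fibulin-1,1.93E+06,2.50E+06,5.05E+06,4.03E+06,2.06E+06,2.03E+06,0.028,2.5
GAAVSNNIVVRPSR,Neuronal cell adhesion molecule,1.15E+06,1.09E+06,1.83E+06,1.12E+06,1.06E+06,9.45E+05,0.028,1.7
SFQTGLFTAAR,Vitamin K-dependent protein S,5.13E+06,1.47E+06,3.81E+06,2.91E+06,7.58E+06,9.33E+05,0.028,2.0
DLGGFDEDAEPR,45 kDa calcium-binding protein,6.98E+04,1.34E+05,1.47E+06,1.26E+06,1.82E+05,3.80E+05,0.030,8.1
VGIPENAPIGTLLLR,Protocadherin gamma-C5,2.25E+05,1.50E+05,1.79E+05,1.58E+05,9.44E+04,7.99E+04,0.040,1.9
FDFNAFR,Mannosyl-oligosaccharide 1.2-alpha-mannosidase IC,7.43E+05,7.37E+05,8.90E+05,1.01E+06,2.57E+06,5.59E+05,0.040,2.9
TFTLLDPK,N-acetylmuramoyl-L-alanine amidase,3.96E+06,5.50E+06,3.04E+06,3.83E+06,1.16E+07,6.44E+06,0.040,3.8
TSDQIHFFFAK,Antithrombin-III,7.63E+06,1.09E+07,8.13E+06,1.43E+07,2.13E+07,9.60E+06,0.040,2.6
TDGAAPNVAPSDVGGGGGR,Contactin-1,7.96E+05,6.87E+05,1.26E+06,7.58E+05,4.69E+05,5.86E+05,0.040,2.7
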