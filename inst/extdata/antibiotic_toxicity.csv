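abbr,name,chem_class,neg_log_ec50_acute,slope_acute,neg_log_ec50_chronic,slope_chronic,e_luc,e_target,e_litr,target_protein
SD,Sulfadiazine,SA,3.03,44.9,4.22,252.57,-31.80,-26.58,-25.46,DHPS
SDX,Sulfadoxine,SA,3.64,65.71,4.05,336.69,-33.77,-29.84,-31.60,DHPS
SIX,Sulfisoxazole,SA,3.54,61.5,4.59,312.87,-34.18,-34.41,-26.31,DHPS
SM,Sulfameter,SA,2.87,57.03,4.30,278.21,-39.32,-24.81,-30.59,DHPS
SMM,Sulfamonomethoxine,SA,3.18,61.17,4.86,299.76,-34.36,-26.23,-27.75,DHPS
SMP,Sulfamethoxypyridazine,SA,2.99,51.97,4.80,248.43,-34.81,-28.80,-29.96,DHPS
SMX,Sulfamethoxazole,SA,3.61,71.35,5.03,350.84,-27.62,-29.75,-25.85,DHPS
SMZ,Sulfamethazine,SA,2.77,37.74,4.30,243.47,-33.85,-30.91,-30.85,DHPS
OMP,Ormethoprim,SAP,3.39,176.07,6.51,1077.8,-37.89,-35.81,-28.94,DHFR
TMP,Trimethoprim,SAP,3.22,169.51,6.48,1006.1,-38.28,-38.23,-31.79,DHFR
CH,Chlortetracycline hydrochloride,TC,4.22,124.11,4.93,1155.3,-59.22,-36.31,-41.69,RIBO30S
DH,Doxycycline hyclate,TC,4.45,155.31,4.80,1099.6,-51.62,-40.38,-38.53,RIBO30S
MH,Minocycline chloride,TC,4.31,89.23,4.42,834.02,-60.55,-32.45,-40.03,RIBO30S
OH,Oxytetracycline hydrochloride,TC,3.76,113.73,3.94,1063.1,-50.37,-40.27,-40.82,RIBO30S
TH,Tetracycline hydrochloride,TC,4.06,121.98,4.30,1155.3,-51.84,-33.68,-39.43,RIBO30S
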