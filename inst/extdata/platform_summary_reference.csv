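platform,day,microtissues_identified,microwells_per_well,pct_empty,pct_filled,volume_per_microtissue,D10,D50,D90,span,predicted_tissue_volume
A400,7,14867,1200,8.82,91.18,0.0015,0.0009,0.0017,0.0033,1.4571,1.6014
A400,14,13210,1200,16.38,83.62,0.0017,0.0010,0.0020,0.0054,2.2674,1.7358
A400,21,12647,1200,21.11,78.89,0.0021,0.0012,0.0024,0.0070,2.4076,1.9432
A800,7,4014,300,10.62,89.38,0.0059,0.0033,0.0068,0.0160,1.8612,1.5851
A800,14,3574,300,26.80,73.20,0.0066,0.0036,0.0084,0.0162,1.5071,1.4487
A800,21,3158,300,29.23,70.77,0.0093,0.0048,0.0118,0.0318,2.2735,1.9731
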