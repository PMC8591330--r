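department,SRob,PDob,PDr_sig_low,PDr_sig_high,RPDr_sig_low,RPDr_sig_high
Quindio,100.0,100.0,66.7,100.0,66.7,100.0
Risaralda,0.0,80.0,100.0,100.0,100.0,100.0
Cordoba,100.0,100.0,100.0,100.0,66.7,0.0
Valle del Cauca,78.6,70.6,36.4,83.3,75.0,50.0
Boyaca,100.0,50.0,75.0,50.0,100.0,0.0
Magdalena,66.7,75.0,50.0,66.7,100.0,0.0
N. Santander,100.0,100.0,50.0,0.0,0.0,100.0
Amazonas,25.0,33.3,0.0,100.0,100.0,80.0
Cundinamarca,66.7,44.4,75.0,50.0,100.0,0.0
Caldas,50.0,50.0,66.7,42.9,50.0,50.0
Guajira,100.0,100.0,66.7,25.0,0.0,0.0
Meta,83.3,55.6,41.7,38.1,0.0,71.4
Antioquia,63.3,61.5,51.2,30.0,51.6,23.1
Santander,60.0,50.0,50.0,37.5,0.0,25.0
Sucre,100.0,100.0,0.0,0.0,0.0,0.0
Cesar,100.0,100.0,0.0,0.0,0.0,0.0
Putumayo,0.0,0.0,100.0,100.0,0.0,0.0
Guainia,0.0,0.0,0.0,0.0,100.0,100.0
Tolima,0.0,33.3,66.7,0.0,60.0,0.0
Huila,0.0,25.0,50.0,0.0,33.3,25.0
Choco,26.7,26.7,11.1,20.0,20.0,25.0
Narino,25.0,55.6,14.3,0.0,26.7,0.0
Bolivar,0.0,0.0,0.0,100.0,0.0,0.0
Caqueta,0.0,0.0,30.0,0.0,20.0,25.0
Cauca,0.0,0.0,50.0,0.0,20.0,0.0
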