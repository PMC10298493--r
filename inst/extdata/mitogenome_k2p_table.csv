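taxon,Andean_tigrina_introgressed,Andean_tigrina,L_guttulus,CA_transAndean_tigrina,L_emiliae,L_c_braccatus,L_guigna,L_wiedii,L_pardalis,L_geoffroyi,L_jacobita,Narino_cat,F_catus,H_yagouaroundi
Andean_tigrina_introgressed,-,0.9,1.2,0.8,0.9,0.9,0.8,0.4,0.3,0.8,0.7,0.7,1.5,1.6
Andean_tigrina,10.6,-,1.4,1.2,1.3,1.3,1.3,1.0,1.0,1.3,1.2,1.1,1.8,2.0
L_guttulus,15.0,16.9,-,1.1,1.3,1.3,1.2,1.2,1.2,1.2,1.2,1.2,2.1,2.1
CA_transAndean_tigrina,7.3,13.2,13.3,-,0.9,0.9,0.7,0.7,0.9,0.7,0.8,0.7,1.5,1.7
L_emiliae,6.4,13.6,16.3,6.9,-,0.0,1.0,1.0,1.0,0.9,1.0,0.9,1.7,1.9
L_c_braccatus,6.4,13.6,16.3,6.9,0.0,-,1.0,1.0,1.0,0.9,1.0,0.9,1.7,1.9
L_guigna,6.8,14.7,15.8,5.3,7.2,7.2,-,0.8,0.9,0.5,0.9,0.9,1.7,1.9
L_wiedii,3.3,11.9,15.2,7.2,7.7,7.7,7.2,-,0.5,0.8,0.8,0.7,1.6,1.6
L_pardalis,2.8,10.6,15.4,8.0,6.9,6.9,7.5,4.4,-,0.9,0.8,0.7,1.5,1.7
L_geoffroyi,6.8,14.3,15.0,5.0,6.5,6.5,2.0,7.2,7.3,-,0.8,0.8,1.5,1.8
L_jacobita,5.7,12.8,15.3,7.7,6.9,6.9,6.9,6.4,6.3,6.7,-,0.9,1.6,1.9
Narino_cat,6.7,13.4,14.4,5.6,6.1,6.1,6.1,7.0,7.6,5.8,7.0,-,1.6,1.7
F_catus,20.8,27.1,29.2,22.3,21.7,21.7,23.1,22.4,21.7,22.4,21.6,21.1,-,1.1
H_yagouaroundi,25.6,32.8,32.4,24.9,25.9,25.9,26.8,25.2,26.6,26.1,26.3,25.1,10.9,-
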