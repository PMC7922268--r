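block,group,method,metric,component_a,component_b,printed,reconciles
extension,varus,ALL,mli_ext,9.8,17.5,7.7,TRUE
extension,valgus,ALL,mli_ext,13.1,14.0,0.5,FALSE
flexion,varus,TEA,mli_flex,10.2,16.6,6.4,TRUE
flexion,valgus,TEA,mli_flex,13.3,15.9,2.6,TRUE
flexion,varus,PCA,mli_flex,10.2,16.2,6.0,TRUE
flexion,valgus,PCA,mli_flex,13.4,15.4,2.0,TRUE
flexion,varus,WSL,mli_flex,10.2,15.7,5.5,TRUE
flexion,valgus,WSL,mli_flex,13.1,14.3,1.2,TRUE
flexion,varus,FEA,mli_flex,9.5,17.6,8.0,FALSE
flexion,valgus,FEA,mli_flex,12.8,16.4,3.6,TRUE
fei,varus,TEA,fei_med,9.8,10.2,-0.4,TRUE
fei,varus,TEA,fei_lat,17.5,16.6,0.8,FALSE
fei,valgus,TEA,fei_med,13.1,13.3,-0.2,TRUE
fei,valgus,TEA,fei_lat,14.2,15.7,-1.5,TRUE
fei,varus,PCA,fei_med,9.8,10.2,-0.4,TRUE
fei,varus,PCA,fei_lat,17.5,16.2,1.2,FALSE
fei,valgus,PCA,fei_med,13.1,13.4,-0.3,TRUE
fei,valgus,PCA,fei_lat,14.2,15.4,-1.2,TRUE
fei,varus,WSL,fei_med,9.8,10.2,-0.3,FALSE
fei,varus,WSL,fei_lat,17.5,15.6,1.8,FALSE
fei,valgus,WSL,fei_med,13.1,13.1,0.0,TRUE
fei,valgus,WSL,fei_lat,14.2,14.3,-0.1,TRUE
fei,varus,FEA,fei_med,9.8,9.5,0.3,TRUE
fei,varus,FEA,fei_lat,17.5,17.6,-0.1,TRUE
fei,valgus,FEA,fei_med,13.1,12.8,0.3,TRUE
fei,valgus,FEA,fei_lat,14.2,16.4,-2.2,TRUE
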