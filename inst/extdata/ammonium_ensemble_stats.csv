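# Published reference ensemble statistics (20 MD geometries, 100 QM waters)
# for solvated ammonium: sample mean and standard deviation in kcal/mol and
# relative standard deviation (percent), per interaction-energy component,
# for a fixed-charge (TIP3P) and a polarizable (POL3) water force field.
ff,stat,ELE,PAU,POL,TOT,DISP,IND
TIP3P,mean,-178.8,48.9,-44.7,-174.4,-40.9,-3.8
TIP3P,sigma,8.0,6.2,3.4,9.0,3.3,0.8
TIP3P,rstd,4.5,12.8,7.6,5.1,8.0,21.1
POL3,mean,-152.0,44.6,-43.3,-150.6,-37.0,-6.3
POL3,sigma,10.5,14.9,7.8,10.3,5.6,2.5
POL3,rstd,5.9,14.7,7.3,4.9,9.3,13.6
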