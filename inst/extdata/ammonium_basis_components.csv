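# Published reference interaction-energy components (kcal/mol) for solvated
# ammonium under a fixed-charge (TIP3P) electrostatic embedding, computed
# with a double-zeta (DZ) and a triple-zeta (TZ) correlation-consistent
# basis, for QM regions of 10-100 water molecules.
basis,n_waters,ELE,PAU,POL,TOT,DISP,IND
DZ,10,-181.8,49.8,-37.5,-169.3,-41.0,3.5
DZ,20,-184.2,50.8,-40.7,-174.0,-42.3,1.5
DZ,30,-182.9,50.7,-41.9,-174.0,-42.0,0.1
DZ,40,-181.4,50.7,-42.7,-173.2,-41.9,-0.9
DZ,50,-181.1,50.8,-43.5,-173.7,-41.9,-1.6
DZ,100,-180.6,50.9,-45.2,-174.8,-41.9,-3.3
TZ,10,-171.8,49.7,-41.9,-163.9,-43.3,1.4
TZ,20,-172.6,50.5,-45.4,-167.5,-44.7,-0.8
TZ,30,-170.5,50.4,-46.8,-166.8,-44.6,-2.3
TZ,40,-168.4,50.4,-47.8,-165.7,-44.4,-3.4
TZ,50,-167.9,50.5,-48.6,-165.9,-44.4,-4.2
TZ,100,-166.3,50.5,-50.6,-166.2,-44.3,-6.2
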