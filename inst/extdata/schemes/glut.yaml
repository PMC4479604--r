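# Glutamate transporter (GluT) scheme.
#
# Simplified uptake model as used in Monte Carlo synapse simulations by
# Franks, Bartol & Sejnowski (2002, Biophys J 83:2333-2348): free transporter
# T binds glutamate (TG); the bound complex either releases the molecule back
# into the extracellular space or translocates it across the membrane
# (removal), restoring the free transporter.
#
# TRANSCRIPTION-TO-VERIFY: rates transcribed from the literature model.
# Units: order 1 in 1/s; order 2 in 1/(M s). T_ref in deg C.
name: glut_franks_2002
citation: "Franks KM, Bartol TM, Sejnowski TJ (2002) Biophys J 83:2333-2348."
T_ref: 23
Q10: 2.5
states: [T, TG]
initial: T
transitions:
  - {from: T,  to: TG, rate: 1.8e7, order: 2}
  - {from: TG, to: T,  rate: 1.8e2, order: 1, releases_ligand: true}
  - {from: TG, to: T,  rate: 1.8e2, order: 1, removes_ligand: true}
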