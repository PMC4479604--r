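# AMPA receptor gating scheme.
#
# Multi-state scheme of Jonas, Major & Sakmann (1993, J Physiol 472:615-663),
# the kinetic model underlying the Hausser & Roth (1997) AMPA receptor
# parameterization: an unliganded closed state (C0), two sequential glutamate
# binding steps (C1, C2), a single conducting state (O) entered from the
# doubly-liganded closed state, and three desensitized closed states
# (C3 singly-liganded; C4, C5 doubly-liganded).
#
# TRANSCRIPTION-TO-VERIFY: rate constants transcribed from the literature
# scheme; users holding the original Hausser & Roth (1997) rate table can
# substitute their own file -- the engine is scheme-agnostic.
#
# Units: order 1 rates in 1/s; order 2 rates in 1/(M s).
# T_ref: room-temperature recordings (deg C). Q10 applied to every rate.
name: ampa_jonas_major_sakmann_1993
citation: >
  Jonas P, Major G, Sakmann B (1993) J Physiol 472:615-663;
  Hausser M, Roth A (1997).
T_ref: 23
Q10: 2.5
states: [C0, C1, C2, C3, C4, C5, O]
initial: C0
open: O
transitions:
  - {from: C0, to: C1, rate: 4.59e6, order: 2}
  - {from: C1, to: C0, rate: 4.26e3, order: 1, releases_ligand: true}
  - {from: C1, to: C2, rate: 2.84e7, order: 2}
  - {from: C2, to: C1, rate: 3.26e3, order: 1, releases_ligand: true}
  - {from: C2, to: O,  rate: 4.24e3, order: 1}
  - {from: O,  to: C2, rate: 9.00e2, order: 1}
  - {from: C1, to: C3, rate: 2.89e3, order: 1}
  - {from: C3, to: C1, rate: 3.92e1, order: 1}
  - {from: C3, to: C4, rate: 1.27e6, order: 2}
  - {from: C4, to: C3, rate: 4.57e1, order: 1, releases_ligand: true}
  - {from: C2, to: C4, rate: 1.72e2, order: 1}
  - {from: C4, to: C2, rate: 7.27e-1, order: 1}
  - {from: C4, to: C5, rate: 1.68e1, order: 1}
  - {from: C5, to: C4, rate: 1.904e2, order: 1}
  - {from: O,  to: C5, rate: 1.77e1, order: 1}
  - {from: C5, to: O,  rate: 4.0,    order: 1}
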