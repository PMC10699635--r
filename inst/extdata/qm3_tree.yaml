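# Packaged haplogroup tree for the Native American Y-chromosome lineage
# Q-M3 and its sublineages.
#
# Spine (fully supported by the published marker hierarchy):
#   Q-M242 > Q-L56 > Q-M346 > Q-L54 > Q-M3 > Q-M848
# Q-Z780 (with Q-CTS11780 below it) is the sibling of Q-M3 under Q-L54.
# Literature sublineage markers CTS11357, SA05, Z19319, Z5915 and Z19483
# are placed as Q-M3 sublineages parallel to Q-M848.
#
# The CO15-CO27 sublineages all fall under the CO24/CO27 clade below
# Q-M848. Their internal branch order is read from a published figure and
# is approximate: two clades are encoded (one with CO15, CO16/CO25, CO19,
# CO21, CO18, CO20; one with CO22, CO26, CO17, CO23), each ordered by the
# lineages' rho-based age estimates. Nodes defined by phyloequivalent
# markers (CO24/CO27, CO16/CO25) list both markers. Amend freely: records
# are (name, markers, parent), the root has no parent.
- name: Q-M242
  markers: [M242]
- name: Q-L56
  markers: [L56]
  parent: Q-M242
- name: Q-M346
  markers: [M346]
  parent: Q-L56
- name: Q-L54
  markers: [L54]
  parent: Q-M346
- name: Q-Z780
  markers: [Z780]
  parent: Q-L54
- name: Q-CTS11780
  markers: [CTS11780]
  parent: Q-Z780
- name: Q-M3
  markers: [M3]
  parent: Q-L54
- name: Q-CTS11357
  markers: [CTS11357]
  parent: Q-M3
- name: Q-SA05
  markers: [SA05]
  parent: Q-M3
- name: Q-Z19319
  markers: [Z19319]
  parent: Q-M3
- name: Q-Z5915
  markers: [Z5915]
  parent: Q-M3
- name: Q-Z19483
  markers: [Z19483]
  parent: Q-M3
- name: Q-M848
  markers: [M848]
  parent: Q-M3
- name: Q-CO24/CO27
  markers: [CO24, CO27]
  parent: Q-M848
- name: Q-CO15
  markers: [CO15]
  parent: Q-CO24/CO27
- name: Q-CO16/CO25
  markers: [CO16, CO25]
  parent: Q-CO15
- name: Q-CO19
  markers: [CO19]
  parent: Q-CO16/CO25
- name: Q-CO21
  markers: [CO21]
  parent: Q-CO19
- name: Q-CO18
  markers: [CO18]
  parent: Q-CO21
- name: Q-CO20
  markers: [CO20]
  parent: Q-CO18
- name: Q-CO22
  markers: [CO22]
  parent: Q-CO24/CO27
- name: Q-CO26
  markers: [CO26]
  parent: Q-CO22
- name: Q-CO17
  markers: [CO17]
  parent: Q-CO26
- name: Q-CO23
  markers: [CO23]
  parent: Q-CO26
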