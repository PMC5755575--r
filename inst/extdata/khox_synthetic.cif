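# Synthetic test structure: potassium hydrogen oxalate-like geometry.
# The cell and space group are the experimental ones; the coordinates and
# displacement parameters are CONSTRUCTED (plausible, not deposited values)
# so that parser, symmetry and fragment-growth behaviour can be exercised
# without any external data.
data_khox_synthetic
_cell_length_a     4.265(1)
_cell_length_b     12.796(1)
_cell_length_c     7.490(1)
_cell_angle_alpha  90
_cell_angle_beta   100.77(1)
_cell_angle_gamma  90
_cell_volume       401.566
_symmetry_space_group_name_H-M 'P 21/c'
_cell_formula_units_Z 4
loop_
_symmetry_equiv_pos_as_xyz
  'x, y, z'
  '-x, y+1/2, -z+1/2'
  '-x, -y, -z'
  'x, -y+1/2, z+1/2'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_U_iso_or_equiv
_atom_site_occupancy
  C1 C 0.4803(4) 0.22630(12) 0.34140(20) 0.0081 1
  C2 C 0.4803(4) 0.34750(12) 0.34140(20) 0.0080 1
  O1 O 0.7312(3) 0.17790(10) 0.34140(17) 0.0102 1
  O2 O 0.2341(3) 0.17480(10) 0.34140(17) 0.0105 1
  O3 O 0.7312(3) 0.39590(10) 0.34140(17) 0.0101 1
  O4 O 0.2388(3) 0.40220(10) 0.34140(17) 0.0108 1
  H1 H 0.0298(80) 0.3866(25) 0.3618(45) 0.0250 1
  K1 K 0.2034(1) 0.53820(4) 0.94190(6) 0.0075 1
loop_
_atom_site_aniso_label
_atom_site_aniso_U_11
_atom_site_aniso_U_22
_atom_site_aniso_U_33
_atom_site_aniso_U_12
_atom_site_aniso_U_13
_atom_site_aniso_U_23
  C1 0.0085(5) 0.0079(5) 0.0080(5) 0.0002(4) 0.0012(4) -0.0001(4)
  C2 0.0083(5) 0.0078(5) 0.0079(5) -0.0001(4) 0.0011(4) 0.0002(4)
  O1 0.0124(4) 0.0089(4) 0.0094(4) 0.0011(3) 0.0021(3) 0.0004(3)
  O2 0.0128(4) 0.0087(4) 0.0099(4) -0.0013(3) 0.0023(3) -0.0006(3)
  O3 0.0119(4) 0.0091(4) 0.0092(4) 0.0009(3) 0.0018(3) 0.0002(3)
  O4 0.0131(4) 0.0090(4) 0.0102(4) -0.0015(3) 0.0025(3) -0.0004(3)
  K1 0.0078(1) 0.0071(1) 0.0077(1) 0.0001(1) 0.0013(1) -0.0002(1)
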