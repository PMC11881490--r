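{
  "n": [209],
  "names": ["mw", "n_rings", "n_rotatable_bonds", "n_hbd", "n_hba", "tpsa", "n_heteroatoms", "logp", "n_stereocenters", "formal_charge", "molar_refractivity", "heavy_atom_count", "count_C", "count_N", "count_O", "count_S", "count_P", "count_F", "count_Cl", "count_Br", "count_I", "count_B", "count_other", "n_bonds", "n_single_bonds", "n_double_bonds", "n_triple_bonds", "n_aromatic_bonds", "n_ring_bonds", "n_ring_atoms", "frac_ring_atoms", "n_aromatic_atoms", "frac_aromatic_atoms", "n_deg1_atoms", "n_deg2_atoms", "n_deg3_atoms", "n_deg4_atoms", "mean_degree", "n_halogen", "frac_heteroatoms", "n_carbonyl", "n_hydroxyl", "n_ether", "n_nitrile", "n_primary_amine", "n_basic_nitrogen", "n_amide", "n_sulfonyl", "n_aromatic_nitrogen", "zagreb_m1", "zagreb_m2", "wiener_index", "balaban_j", "chi0", "chi1", "chi0v", "chi1v", "kappa1", "kappa2", "kappa3", "graph_diameter", "graph_radius", "mean_topological_distance", "platt_index", "harary_index", "ats_mass_1", "ats_mass_2", "ats_mass_3", "ats_mass_4", "ats_mass_5", "ats_mass_6", "ats_mass_7", "ats_mass_8", "ats_charge_1", "ats_charge_2", "ats_charge_3", "ats_charge_4", "ats_charge_5", "ats_charge_6", "ats_charge_7", "ats_charge_8", "ats_eneg_1", "ats_eneg_2", "ats_eneg_3", "ats_eneg_4", "ats_eneg_5", "ats_eneg_6", "ats_eneg_7", "ats_eneg_8", "ats_degree_1", "ats_degree_2", "ats_degree_3", "ats_degree_4", "ats_degree_5", "ats_degree_6", "ats_degree_7", "ats_degree_8", "atsc_mass_1", "atsc_mass_2", "atsc_mass_3", "atsc_mass_4", "atsc_mass_5", "atsc_mass_6", "atsc_mass_7", "atsc_mass_8", "atsc_charge_1", "atsc_charge_2", "atsc_charge_3", "atsc_charge_4", "atsc_charge_5", "atsc_charge_6", "atsc_charge_7", "atsc_charge_8", "atsc_eneg_1", "atsc_eneg_2", "atsc_eneg_3", "atsc_eneg_4", "atsc_eneg_5", "atsc_eneg_6", "atsc_eneg_7", "atsc_eneg_8", "atsc_degree_1", "atsc_degree_2", "atsc_degree_3", "atsc_degree_4", "atsc_degree_5", "atsc_degree_6", "atsc_degree_7", "atsc_degree_8", "geary_mass_1", "geary_mass_2", "geary_mass_3", "geary_mass_4", "geary_mass_5", "geary_mass_6", "geary_mass_7", "geary_mass_8", "geary_charge_1", "geary_charge_2", "geary_charge_3", "geary_charge_4", "geary_charge_5", "geary_charge_6", "geary_charge_7", "geary_charge_8", "geary_eneg_1", "geary_eneg_2", "geary_eneg_3", "geary_eneg_4", "geary_eneg_5", "geary_eneg_6", "geary_eneg_7", "geary_eneg_8", "geary_degree_1", "geary_degree_2", "geary_degree_3", "geary_degree_4", "geary_degree_5", "geary_degree_6", "geary_degree_7", "geary_degree_8", "n_pairs_dist1", "n_pairs_dist2", "n_pairs_dist3", "n_pairs_dist4", "n_pairs_dist5", "n_pairs_dist6", "n_pairs_dist7", "n_pairs_dist8", "n_pairs_dist9", "n_pairs_dist10", "n_pairs_dist11", "n_pairs_dist12", "n_pairs_dist13", "n_pairs_dist14", "n_pairs_dist15", "n_hetero_pairs_dist1", "n_hetero_pairs_dist2", "n_hetero_pairs_dist3", "n_hetero_pairs_dist4", "n_hetero_pairs_dist5", "n_hetero_pairs_dist6", "n_hetero_pairs_dist7", "n_hetero_pairs_dist8", "n_hetero_pairs_dist9", "n_hetero_pairs_dist10", "cc_bonds", "cn_bonds", "co_bonds", "cs_bonds", "c_halogen_bonds", "nn_bonds", "no_bonds", "aromatic_cc_bonds", "aromatic_cn_bonds", "n_ring_fusion_atoms", "frac_csp3", "mean_partial_charge", "max_partial_charge", "min_partial_charge", "sum_abs_partial_charge", "mean_atomic_mass", "n_implicit_h", "n_hbd_atoms", "n_hba_atoms", "n_hydrophobic_atoms", "mw_per_atom", "log_heavy_atom_count", "branch_fraction"]
}
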