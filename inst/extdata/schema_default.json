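{
  "name": ["ASA_all_abs", "ASA_all_rel", "ASA_nonpolar_abs", "ASA_nonpolar_rel", "ASA_polar_abs", "ASA_polar_rel", "ASA_side_abs", "ASA_side_rel", "uASA_all_abs", "uASA_all_rel", "uASA_nonpolar_abs", "uASA_nonpolar_rel", "uASA_polar_abs", "uASA_polar_rel", "uASA_side_abs", "uASA_side_rel", "dASA_all_abs", "dASA_all_rel", "dASA_nonpolar_abs", "dASA_nonpolar_rel", "dASA_polar_abs", "dASA_polar_rel", "dASA_side_abs", "dASA_side_rel", "SS_tco", "SS_kappa", "SS_alpha", "SS_phi", "SS_psi", "SS_water", "DPX_mean_bound", "DPX_sd_bound", "DPX_mean_unbound", "DPX_sd_unbound", "DPX_d_mean", "DPX_d_sd", "CX_mean_bound", "CX_sd_bound", "CX_mean_unbound", "CX_sd_unbound", "CX_d_mean", "CX_d_sd", "Hbond_count", "wt_ASA_Ea_L1", "wt_ASA_Ea_L2", "wt_ASA_Ea_L3", "wt_ASA_Ea_sd", "wt_ASA_Ea_mean", "wt_ASA_Ed", "wt_ASA_ent_shannon", "wt_ASA_ent_sure", "wt_ASA_ent_threshold", "wt_ASA_ent_norm", "wt_ASA_ent_logenergy", "wpt_ASA_energy_total", "wpt_ASA_node_1", "wpt_ASA_node_2", "wpt_ASA_node_3", "wpt_ASA_node_4", "wpt_ASA_node_5", "wpt_ASA_node_6", "wpt_ASA_node_7", "wpt_ASA_node_8", "wpt_ASA_ent_shannon", "wpt_ASA_ent_sure", "wpt_ASA_ent_threshold", "wpt_ASA_ent_norm", "wpt_ASA_ent_logenergy", "wpt_ASA_rel_node_1", "wpt_ASA_rel_node_2", "wpt_ASA_rel_node_3", "wpt_ASA_rel_node_4", "wpt_ASA_rel_node_5", "wpt_ASA_rel_node_6", "wpt_ASA_rel_node_7", "wpt_ASA_rel_node_8", "wt_uASA_Ea_L1", "wt_uASA_Ea_L2", "wt_uASA_Ea_L3", "wt_uASA_Ea_sd", "wt_uASA_Ea_mean", "wt_uASA_Ed", "wt_uASA_ent_shannon", "wt_uASA_ent_sure", "wt_uASA_ent_threshold", "wt_uASA_ent_norm", "wt_uASA_ent_logenergy", "wpt_uASA_energy_total", "wpt_uASA_node_1", "wpt_uASA_node_2", "wpt_uASA_node_3", "wpt_uASA_node_4", "wpt_uASA_node_5", "wpt_uASA_node_6", "wpt_uASA_node_7", "wpt_uASA_node_8", "wpt_uASA_ent_shannon", "wpt_uASA_ent_sure", "wpt_uASA_ent_threshold", "wpt_uASA_ent_norm", "wpt_uASA_ent_logenergy", "wpt_uASA_rel_node_1", "wpt_uASA_rel_node_2", "wpt_uASA_rel_node_3", "wpt_uASA_rel_node_4", "wpt_uASA_rel_node_5", "wpt_uASA_rel_node_6", "wpt_uASA_rel_node_7", "wpt_uASA_rel_node_8", "wt_dASA_Ea_L1", "wt_dASA_Ea_L2", "wt_dASA_Ea_L3", "wt_dASA_Ea_sd", "wt_dASA_Ea_mean", "wt_dASA_Ed", "wt_dASA_ent_shannon", "wt_dASA_ent_sure", "wt_dASA_ent_threshold", "wt_dASA_ent_norm", "wt_dASA_ent_logenergy", "wpt_dASA_energy_total", "wpt_dASA_node_1", "wpt_dASA_node_2", "wpt_dASA_node_3", "wpt_dASA_node_4", "wpt_dASA_node_5", "wpt_dASA_node_6", "wpt_dASA_node_7", "wpt_dASA_node_8", "wpt_dASA_ent_shannon", "wpt_dASA_ent_sure", "wpt_dASA_ent_threshold", "wpt_dASA_ent_norm", "wpt_dASA_ent_logenergy", "wpt_dASA_rel_node_1", "wpt_dASA_rel_node_2", "wpt_dASA_rel_node_3", "wpt_dASA_rel_node_4", "wpt_dASA_rel_node_5", "wpt_dASA_rel_node_6", "wpt_dASA_rel_node_7", "wpt_dASA_rel_node_8", "wt_SS_Ea_L1", "wt_SS_Ea_L2", "wt_SS_Ea_L3", "wt_SS_Ea_sd", "wt_SS_Ea_mean", "wt_SS_Ed", "wt_SS_ent_shannon", "wt_SS_ent_sure", "wt_SS_ent_threshold", "wt_SS_ent_norm", "wt_SS_ent_logenergy", "wpt_SS_energy_total", "wpt_SS_node_1", "wpt_SS_node_2", "wpt_SS_node_3", "wpt_SS_node_4", "wpt_SS_node_5", "wpt_SS_node_6", "wpt_SS_node_7", "wpt_SS_node_8", "wpt_SS_ent_shannon", "wpt_SS_ent_sure", "wpt_SS_ent_threshold", "wpt_SS_ent_norm", "wpt_SS_ent_logenergy", "wpt_SS_rel_node_1", "wpt_SS_rel_node_2", "wpt_SS_rel_node_3", "wpt_SS_rel_node_4", "wpt_SS_rel_node_5", "wpt_SS_rel_node_6", "wpt_SS_rel_node_7", "wpt_SS_rel_node_8", "imf_1_ASA_meanValue", "imf_1_ASA_variance", "imf_1_ASA_energy", "imf_1_ASA_autocorr", "imf_2_ASA_meanValue", "imf_2_ASA_variance", "imf_2_ASA_energy", "imf_2_ASA_autocorr", "imf_3_ASA_meanValue", "imf_3_ASA_variance", "imf_3_ASA_energy", "imf_3_ASA_autocorr", "imf_1_uASA_meanValue", "imf_1_uASA_variance", "imf_1_uASA_energy", "imf_1_uASA_autocorr", "imf_2_uASA_meanValue", "imf_2_uASA_variance", "imf_2_uASA_energy", "imf_2_uASA_autocorr", "imf_3_uASA_meanValue", "imf_3_uASA_variance", "imf_3_uASA_energy", "imf_3_uASA_autocorr", "imf_1_dASA_meanValue", "imf_1_dASA_variance", "imf_1_dASA_energy", "imf_1_dASA_autocorr", "imf_2_dASA_meanValue", "imf_2_dASA_variance", "imf_2_dASA_energy", "imf_2_dASA_autocorr", "imf_3_dASA_meanValue", "imf_3_dASA_variance", "imf_3_dASA_energy", "imf_3_dASA_autocorr", "imf_1_SS_meanValue", "imf_1_SS_variance", "imf_1_SS_energy", "imf_1_SS_autocorr", "imf_2_SS_meanValue", "imf_2_SS_variance", "imf_2_SS_energy"],
  "block": ["conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "conventional", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "wavelet", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd", "emd"]
}
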