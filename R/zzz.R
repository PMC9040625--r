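# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", ".N", ".SD", "peptide", "protein_id", "sample_id", "condition",
  "replicate", "level", "light_intensity", "heavy_intensity", "intensity",
  "precursor_charge", "pass", "lloq_light", "lloq_heavy", "conc", "amount",
  "gdcw", "ratio", "prot_mean", "pct_diff", "cv", "status", "n_peptides",
  "n_cond", "pep_int", "sil_conc", "molecular_weight", "mass_g_per_gdcw",
  "mass_ug", "category", "w", "fraction", "d", "run", "n", "alt", "rank",
  "mean_rank", "overall", "ref_flux", "nonzero", "above", "reaction_id",
  "alternative_index", "membrane_flag", "value", "flux_p", "flux_q",
  "relative_intensity", "kappa", "bio_eff", "conc_rep", "phi", "light",
  "heavy", "weight", "fragment_index", "base_conc", "kapp", "flux_mean",
  "enzyme_conc", "sd"))
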