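{
  "description": "SYNTHETIC chromophore extinction/absorption compilation for near-infrared tissue simulation (600-1200 nm, 2-nm grid).",
  "provenance": "Not a digitization of any published table. Anchor points follow the qualitative shapes of standard compilations (oxy/deoxy-hemoglobin molar extinction; pure water and pure fat absorption), interpolated with shape-preserving cubics and then calibrated: hemoglobin columns were multiplied by a smooth wavelength-dependent factor so that the reference composition reproduces the target total absorption below.",
  "columns": {
    "wavelength_nm": "vacuum wavelength, nm",
    "eps_hbo": "molar extinction of oxyhemoglobin, base-10, cm^-1 M^-1",
    "eps_hbr": "molar extinction of deoxyhemoglobin, base-10, cm^-1 M^-1",
    "mua_water": "absorption coefficient of pure water, natural log, cm^-1",
    "mua_fat": "absorption coefficient of pure fat, natural log, cm^-1"
  },
  "log_base_hemoglobin": 10,
  "ln10_conversion_applied_downstream": true,
  "calibration": {
    "reference_composition": {
      "hbt_uM": 80,
      "so2": 0.625,
      "f_water": 0.75,
      "f_fat": 0.2
    },
    "target_total_mua_cm1": {
      "nm765": 0.19,
      "nm785": 0.17,
      "nm850": 0.2,
      "nm1064": 0.18
    },
    "hemoglobin_scale_factors": {
      "nm765": 0.9792,
      "nm785": 0.9795,
      "nm850": 0.9781,
      "nm1064": 0.4114
    }
  }
}
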