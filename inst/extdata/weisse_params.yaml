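# Wild-type parameter set of the coarse-grained whole-cell growth model
# (nutrient import -> energy -> transcription -> ribosome-mRNA binding ->
# translation). Units: minutes and molecules per cell. asset_version tracks
# revisions of this file, not of the package.
asset_version: 1
params:
  s_ext: 1.0e4      # external nutrient concentration (held constant)
  v_t: 726          # transporter max import rate, 1/min
  K_t: 1000         # transport Michaelis constant (external nutrient)
  v_m: 5800         # metabolic enzyme max rate, 1/min
  K_m: 1000         # metabolism Michaelis constant (internal nutrient)
  n_s: 0.5          # energy units yielded per metabolised nutrient
  w_r: 930          # maximal ribosomal transcription rate, mRNA/min
  w_e: 4.14         # maximal transporter/enzyme transcription rate, mRNA/min
  w_q: 948.93       # maximal housekeeping transcription rate, mRNA/min
  theta_x: 4.38     # transcription energy threshold, non-ribosomal classes;
                    # gamma = 1/theta_x
  theta_r: 426.87   # transcription energy threshold, ribosomal class; the
                    # theta_r >> theta_x asymmetry down-regulates ribosome
                    # production when energy is scarce
  K_q: 152219       # housekeeping autoinhibition threshold (molecules)
  h_q: 4            # housekeeping autoinhibition Hill exponent
  k_b: 1            # ribosome-mRNA binding rate, 1/(molecule min)
  k_u: 1            # ribosome-mRNA unbinding rate, 1/min
  d_m: 0.1          # mRNA degradation rate, 1/min
  g_max: 1260       # maximal translation elongation rate, aa/min
  K_p: 7            # translation energy Michaelis constant
  M: 1.0e8          # total cell mass, amino acids
  n_r: 7549         # ribosome length, aa
  n_x: 300          # non-ribosomal protein length, aa
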