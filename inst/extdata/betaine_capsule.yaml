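# Betaine-capsule run configuration (units in the key suffixes)
physical:
  D_m2_s: 1.0e-9        # amino-acid-like diffusivity
  temperature_K: 293
  eta_Pa_s: 1.0e-3
  c0_mM: 100            # capsule concentration
  V_mL: 1               # capsule volume (authoritative for total moles)
  a_major_mm: 16        # full horizontal axis of the prolate capsule
  a_minor_mm: 6.3
  depth_mm: 5           # depth of the capsule center below the interface
  c_star_uM: 10         # leg sensory threshold (permissive end of 10-100 uM)
  t_max_s: 1800         # 30-minute trial
  layer_depth_mm: 0.5   # surface sand layer sampled by the legs
scenario: free_interface
seed: 1
sweep:
  c0_mM: [1, 10, 100]
  depth_mm: [5, 10]
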