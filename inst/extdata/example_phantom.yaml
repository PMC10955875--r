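# Example phantom: two tungsten electrodes (1p1g) in muscle-like tissue.
# Units are SI throughout.
medium:
  grid_shape: [129, 129]
  pixel_size: 0.00025        # 0.25 mm pixels, 32 mm domain
  sigma: 0.5                 # S/m
  v_s: 1497                  # m/s
electrodes:
  centers: [[-0.0021, 0.0], [0.0021, 0.0]]
  radius: 0.0005             # 0.5 mm tips
  mode: 1p1g
  voltage: 1200
pulse:
  amplitude: 1200
  width: 1.0e-7              # 100 ns FWHM
  rise_time: 1.5e-8          # 15 ns
  rep_rate: 1000
array:
  n_elements: 64
  ring_radius: 0.05
  sampling_rate: 4.0e+7
  n_samples: 2900
snr_db: 30
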