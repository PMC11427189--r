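# Example run configuration for the sao CLI and read_sao_config().
optics:
  wavelength: 0.488       # um
  dm_gain: 0.28           # commanded-um -> pupil-OPD gain
  grid_size: 64
  pupil_radius: 31
  fiber_diameter: 4       # Airy disk diameters
  sample:
    kind: fibers
    size: 64
    seed: 99
env:
  aberration_config: train_uniform
  target_indices: [4, 5, 6]
  noise_indices: [16, 17, 18]
  bias: 0.5               # observation bias, um
training:
  episodes: 3000
  warmup_episodes: 300
  noise_profiles: 10
  hidden: 48
  critic_hidden: 48
  batch_size: 96
  updates_per_episode: 8
  actor_updates_per_episode: 3
  lr_actor: 3.0e-4
  lr_critic: 1.0e-3
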