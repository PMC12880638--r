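# Example subtask configuration for read_env_config()
difficulty: hard
input_noise: true
episode_length: 470
corridor_width: 9
reward_mode: dense
seed: 42
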