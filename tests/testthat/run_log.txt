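tauavrami 0.1.0
R 4.3.3
command: project
seed: (none)
config echo:
  field = missing.vtu
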