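# Shared constants (this file collates first).

# months <-> days conversion used everywhere
DAYS_PER_MONTH <- 30.4375
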