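[2026-09-22 21:51:13] cmd=no-such-command seed=1 opts=
[2026-09-22 22:14:00] cmd=no-such-command seed=1 opts=
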