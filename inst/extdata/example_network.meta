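network_id = demo_meadow
location = synthetic demonstration community
quantitative = true
exotic_plants = Trifolium_repens, Cirsium_arvense
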