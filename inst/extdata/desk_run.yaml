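# Desk-scale run configuration: 64 px patches, 32 px spots.
patch_size_px: 64
spot_size_px: 32
epochs: 12
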