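# Desk-scale simulated cohort: four pseudo-patients, 64 px patches.
n_patients: 4
spots_per_patient: 400
patch_size_px: 64
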