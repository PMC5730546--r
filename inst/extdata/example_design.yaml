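# Example copper immobilization/behavior assay layout: eight concentration
# groups (control + 7 doses) in clusters of three chambers, five neonates
# per chamber, clips sampled hourly early and at the 24/48 h endpoints.
name: copper_example
units: mg/L
concentrations: [0, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1.0]
replicates: 3
animals_per_chamber: 5
sampling_times_h: [1, 2, 4, 8, 24, 48]
duration_s: 30
fps: 30
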