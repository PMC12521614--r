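# Example pipeline configuration (see ?runConfig for all keys).
# Paths are resolved relative to the working directory.
scan_table: scan.csv
conservation_table: conservation.csv
n_bins: 10
bin_range: [5, 11]
exclusion_threshold: 1.0
neutral_threshold: 0.70
toggle_threshold: 0.6667
rheostat_threshold: 0.5
seed: 1
output_dir: results
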