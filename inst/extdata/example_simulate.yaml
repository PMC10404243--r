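# Example pipeline configuration: simulate the Amazon-like toy scenario.
#   Rscript inst/cli/dynlgcp.R simulate inst/extdata/example_simulate.yaml
# then point a fit config at the produced events.csv / boundary.geojson.
seed: 1
frequency: quarterly
scenario: amazon
intercept: -4.1
output_dir: dynlgcp_output
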