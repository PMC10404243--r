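# Example fit configuration (paths relative to this file's directory).
# Run the simulate example first so the inputs below exist.
seed: 1
frequency: quarterly
events: dynlgcp_output/events.csv
boundary: dynlgcp_output/boundary.geojson
mesh:
  max_edge_inner: 25
  extension_fraction: 0.15
components:
  trend: true
  seasonal:
    period: 4
    estimate_phi: false
  cycle: true
  field: false
output_dir: dynlgcp_fit
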