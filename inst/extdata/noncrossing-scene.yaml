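# Sideways-moving object at fixed depth over an approaching background
# (non-crossing start). Units: metres unless suffixed _deg.
camera: {focal_length_m: 0.0187, width_m: 0.01}
background: {type: translational, d0: 10, v: [0.21, 0, 2]}
imo:
  region: {x_deg: 0.6, y_deg: 0, width_deg: 10, height_deg: 10}
  layer: {type: translational, d0: 5, v: [-0.71, 0, 0]}
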