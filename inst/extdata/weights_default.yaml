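w_direct: 0.0973887115234022
w_horizontal: 0.0973887115234022
w_vertical: 0.0973887115234022
w_radial: 0.0973887115234022
w_area: 0.3112463104632251
w_circumference: 0.29919884344316605
scale_max: 15.0
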