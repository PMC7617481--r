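profile,bin_center_deg,value
short_ee_orientation,11.25,0.30
short_ee_orientation,45,0.17
short_ee_orientation,78.75,0.09
short_ee_direction,11.25,0.32
short_ee_direction,45,0.18
short_ee_direction,90,0.10
short_ee_direction,135,0.16
short_ee_direction,168.75,0.26
long_coaxial_orientation,11.25,0.22
long_coaxial_orientation,45,0.12
long_coaxial_orientation,78.75,0.08
long_coorthogonal_orientation,11.25,0.11
long_coorthogonal_orientation,45,0.10
long_coorthogonal_orientation,78.75,0.09
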