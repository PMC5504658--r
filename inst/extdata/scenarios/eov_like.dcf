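label: eov_like
weeks: 51
weekday_profile: 206 193 182 171 150 86 34
trend_per_week: 0
annual_amplitude: 10
ar_coefficient: 0.5
noise_sd: 15
holiday_weeks: 5:1:0.6;5:2:0.6;18:4:0.5;31:3:0.5;31:4:0.5
seed: 20140106
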