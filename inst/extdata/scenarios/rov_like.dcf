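label: rov_like
weeks: 51
weekday_profile: 173 178 145 161 163 18 11
trend_per_week: 0
annual_amplitude: 8
ar_coefficient: 0.4
noise_sd: 10
holiday_weeks: 5:1:0.6;5:2:0.6;18:4:0.5;31:3:0.5
seed: 20140107
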