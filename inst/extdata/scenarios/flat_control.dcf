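label: flat_control
weeks: 51
weekday_profile: 150 150 150 150 150 150 150
trend_per_week: 0
annual_amplitude: 0
ar_coefficient: 0
noise_sd: 10
holiday_weeks:
seed: 20140108
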