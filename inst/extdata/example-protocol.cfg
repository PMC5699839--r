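# Example bipolar square-wave protocol (±40 mV at 100 kHz sampling).
# v_stim_mV is the FULL step amplitude (peak-to-peak of the bipolar wave).
v_stim_mV  = 80
period_ms  = 0.56
f_samp_kHz = 100
n_periods  = 4
holding_mV = 0
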