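raw_name	canonical_name	flag
paracetamol	acetaminophen	synonym
aspirin	acetylsalicylic acid	synonym
beta blocker nos		ambiguous
pain reliever nos		ambiguous
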