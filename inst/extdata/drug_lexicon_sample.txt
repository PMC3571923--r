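# sample drug lexicon: canonical|form1|form2|...
verapamil|Calan|Isoptin
midazolam|Versed
ketoconazole|Nizoral
st john's wort|hypericum
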