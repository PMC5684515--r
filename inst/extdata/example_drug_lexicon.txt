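# Example medication lexicon: canonical name, then comma-separated surface
# variants. Single-token variants only (the matcher is token-equality based).
acetaminophen: tylenol, paracetamol
ibuprofen: advil, motrin
ondansetron: zofran
doxylamine: unisom
sertraline: zoloft
fluoxetine: prozac
levothyroxine: synthroid
omeprazole: prilosec
diphenhydramine: benadryl
amoxicillin: amoxil
metformin: glucophage
ranitidine: zantac
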