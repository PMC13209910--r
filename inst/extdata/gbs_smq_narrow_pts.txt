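# Guillain-Barre syndrome SMQ (code 20000131), narrow scope.
# Nine preferred terms; one per line, '#' starts a comment.
Acute motor axonal neuropathy
Acute motor-sensory axonal neuropathy
Bickerstaff's encephalitis
Chronic inflammatory demyelinating polyradiculoneuropathy
Demyelinating polyneuropathy
Guillain-Barre syndrome
Miller Fisher syndrome
Subacute inflammatory demyelinating polyneuropathy
Zika virus associated Guillain-Barre syndrome
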