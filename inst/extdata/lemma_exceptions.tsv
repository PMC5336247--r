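children	child
women	woman
men	man
feet	foot
teeth	tooth
mice	mouse
analyses	analysis
sera	serum
data	data
media	media
fetuses	fetus
foci	focus
criteria	criterion
was	be
were	be
is	be
are	be
am	be
been	be
being	be
has	have
had	have
having	have
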