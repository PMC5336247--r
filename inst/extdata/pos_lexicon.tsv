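the	DT
a	DT
an	DT
this	DT
these	DT
those	DT
of	IN
in	IN
on	IN
for	IN
with	IN
from	IN
by	IN
to	TO
at	IN
into	IN
via	IN
among	IN
between	IN
during	IN
after	IN
before	IN
and	CC
or	CC
but	CC
we	PRP
it	PRP
they	PRP
is	VBZ
are	VBP
was	VBD
were	VBD
be	VB
been	VBN
being	VBG
has	VBZ
have	VBP
had	VBD
can	MD
may	MD
could	MD
should	MD
will	MD
not	RB
also	RB
however	RB
significantly	RB
respectively	RB
higher	JJR
lower	JJR
high	JJ
low	JJ
human	JJ
significant	JJ
mean	JJ
median	JJ
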