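# Toy English stand-in lexicon: word <TAB> category label(s).
# Covers all 7 main categories and representative subcategories.
i	first_person
me	first_person
my	first_person
we	first_person
us	first_person
our	first_person
myself	first_person
mine	first_person
you	second_person
your	second_person
yours	second_person
he	third_person
she	third_person
they	third_person
him	third_person
her	third_person
them	third_person
his	third_person
their	third_person
the	article
a	article
an	article
no	negate
not	negate
never	negate
none	negate
many	quant
few	quant
all	quant
some	quant
much	quant
in	prep
on	prep
at	prep
with	prep
from	prep
to	prep
and	conj
but	conj
or	conj
because	conj	cause
family	family
mother	family
father	family
sister	family
brother	family
friend	friend
buddy	friend
neighbor	friend
people	humans
person	humans
human	humans
happy	posemo
good	posemo
love	posemo
hope	posemo
glad	posemo
nice	posemo
better	posemo
joy	posemo
sad	sad
cry	sad
tears	sad
grief	sad
lonely	sad
hopeless	sad
miserable	sad
afraid	anx
worry	anx
nervous	anx
fear	anx
anxious	anx
panic	anx
angry	anger
hate	anger
annoyed	anger
rage	anger
think	insight
know	insight
understand	insight
realize	insight
believe	insight
cause	cause
effect	cause
reason	cause
hence	cause
always	certain
sure	certain
certain	certain
maybe	tentat
perhaps	tentat
guess	tentat
seem	tentat
see	see
look	see
watch	see
view	see
hear	hear
listen	hear
sound	hear
feel	feel
touch	feel
warm	feel	posemo
body	body
head	body
heart	body
sleep	body
tired	body
sick	health
doctor	health
medicine	health
pain	health
depression	health
illness	health
eat	ingest
drink	ingest
food	ingest
go	motion
come	motion
walk	motion
arrive	motion
here	space
there	space
home	space
school	space
up	space
down	space
now	time
then	time
today	time
before	time
after	time
year	time
day	time
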