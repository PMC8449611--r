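a
about
after
again
against
almost
also
always
am
an
and
any
anyone
are
articles
as
ask
asked
available
away
back
bad
be
because
been
before
being
best
better
between
body
both
but
buy
can
cannot
care
chronic
clinical
comment
comments
condition
could
daily
day
days
did
discussed
do
doctor
doctors
does
dosage
dose
doses
down
drug
drugs
during
each
effect
effects
else
even
ever
every
experience
family
feel
feeling
felt
few
find
fine
first
forum
found
friend
friends
from
general
generic
get
gets
getting
give
given
going
good
got
had
half
has
have
having
health
help
helped
helpful
helps
her
here
him
his
home
hope
hospital
hour
hours
how
husband
if
information
into
issue
issues
it
its
just
know
knowledge
last
less
life
like
little
long
looking
made
make
manage
managed
many
may
medical
medication
medications
medicine
mention
mentioned
mild
might
mine
month
months
more
morning
most
mother
much
must
my
myself
need
needed
never
new
next
night
no
not
nothing
now
of
off
often
old
on
once
one
only
or
other
our
out
over
own
patient
patients
people
per
pharmacy
pill
pills
please
prescribe
prescribed
prescription
question
read
really
recommend
recommended
relief
research
researchers
said
same
saw
say
says
see
seen
severe
she
should
side
since
sister
sleep
so
some
someone
something
sometimes
soon
started
starting
still
stop
stopped
studied
studies
study
such
sure
switched
symptom
symptoms
take
taken
takes
taking
tablet
tablets
than
that
the
their
them
then
there
these
they
thing
things
think
this
those
though
thought
through
time
times
tired
to
today
told
took
treat
treated
treatment
tried
try
trying
up
upset
us
use
used
uses
using
usual
usually
version
very
visit
want
wanted
was
way
we
week
weeks
well
went
were
what
when
where
which
while
who
why
widely
wife
will
with
without
wondering
work
worked
working
works
worse
would
year
years
yes
yet
you
your
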